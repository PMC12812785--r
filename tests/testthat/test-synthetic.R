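# The synthetic twin-cohort generator and its implied covariance.

test_that("expected covariance matches the brute-force innovation-map oracle", {
  for (seed in c(3, 17, 99)) {
    spec <- random_genspec(seed)
    for (z in c("MZ", "DZ")) {
      got <- unname(build_expected_cov(spec, z))
      want <- oracle_expected_cov(spec, z)
      expect_lt(max(abs(got - want)), 1e-10)
      expect_lt(max(abs(got - t(got))), 1e-12)
      expect_gt(min(eigen(got, symmetric = TRUE, only.values = TRUE)$values),
                -1e-10)
    }
  }
})

test_that("component limits of the cross-twin structure are exact", {
  # E only: no cross-twin covariance for either zygosity
  eonly <- single_component_spec("E")
  for (z in c("MZ", "DZ"))
    expect_equal(max(abs(build_expected_cov(eonly, z)[1:6, 7:12])), 0)
  # A only, MZ: cross-twin block equals within-twin block
  aonly <- single_component_spec("A")
  Smz <- build_expected_cov(aonly, "MZ")
  expect_equal(Smz[1:6, 7:12], Smz[1:6, 1:6], ignore_attr = TRUE)
  # A only, zero transitions, identity sigma1, DZ: wave-1 cross = 0.5 I
  astat <- single_component_spec("A", B12 = matrix(0, 2, 2),
                                 B23 = matrix(0, 2, 2))
  Sdz <- build_expected_cov(astat, "DZ")
  expect_equal(Sdz[1:2, 7:8], 0.5 * diag(2), ignore_attr = TRUE)
})

test_that("phenotypic blocks are zygosity-invariant and the DZ A-channel is halved", {
  spec <- random_genspec(7)
  Smz <- build_expected_cov(spec, "MZ")
  Sdz <- build_expected_cov(spec, "DZ")
  expect_equal(Smz[1:6, 1:6], Sdz[1:6, 1:6])
  expect_equal(Smz[7:12, 7:12], Smz[1:6, 1:6],
               ignore_attr = TRUE)
  # the A channel: difference of cross blocks between full spec and its
  # A-zeroed version must halve exactly from MZ to DZ
  specE <- spec
  zero2 <- matrix(0, 2, 2)
  specE$processes$A <- component_process("A", zero2, zero2, zero2,
                                         zero2, zero2)
  a_mz <- Smz[1:6, 7:12] - build_expected_cov(specE, "MZ")[1:6, 7:12]
  a_dz <- Sdz[1:6, 7:12] - build_expected_cov(specE, "DZ")[1:6, 7:12]
  expect_equal(a_dz, 0.5 * a_mz)
})

test_that("invalid inputs are rejected with informative errors", {
  spec <- random_genspec(1)
  expect_error(build_expected_cov(spec, "XX"), "zygosity")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(component_process("A", bad, diag(2), diag(2), diag(2),
                                 diag(2)), "sigma1")
  expect_error(gen_spec(spec$processes, prop_mz = 1.4), "prop_mz")
})

test_that("simulated cohorts are deterministic and demographically faithful", {
  spec <- random_genspec(5)
  spec$n_pairs <- 400L
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 800L)
  expect_true(all(table(c1$pair_id) == 2))
  allmz <- spec; allmz$prop_mz <- 1
  expect_false("DZ" %in% simulate_cohort(allmz)$zygosity)
  # MZ co-twins share sex
  mz <- c1[c1$zygosity == "MZ", ]
  expect_true(all(tapply(mz$sex, mz$pair_id, function(s) length(unique(s))) == 1))
})

test_that("empirical MZ moments converge to the implied covariance", {
  spec <- default_genspec("twin", n_pairs = 50000L, miss_wave = c(0, 0, 0),
                          attrition3 = 0, age_effect = c(0, 0),
                          sex_effect = c(0, 0), seed = 42L)
  co <- simulate_cohort(spec)
  co <- add_home_composite(co)  # recovers the latent H up to scaling
  mats <- twinclpm:::pair_matrix(co, "twin")
  emp <- stats::cov(mats$MZ)
  # the home composite is re-standardized, so compare correlations
  want <- stats::cov2cor(build_expected_cov(spec, "MZ"))
  got <- stats::cov2cor(emp)
  n_mz <- nrow(mats$MZ)
  # elementwise 3 monte-carlo SEs for a correlation
  expect_lt(max(abs(got - want)), 3 * 1.3 / sqrt(n_mz) + 0.005)
})

test_that("item generation reproduces loadings and respects edge cases", {
  spec <- default_genspec("twin", n_pairs = 25000L, miss_wave = c(0, 0, 0),
                          attrition3 = 0, seed = 8L,
                          item_loadings = list(c(0.7, 0.6, 0.5), NULL, NULL))
  co <- simulate_cohort(spec)
  co2 <- simulate_items(co, spec)
  f <- scale(co2$p_twin_9)
  for (k in 1:3) {
    r <- stats::cor(co2[[paste0("item_twin_9_", k)]], f)
    expect_lt(abs(r - c(0.7, 0.6, 0.5)[k]), 3 / sqrt(nrow(co2)) + 0.01)
  }
  # loading of exactly 1 copies the factor
  spec1 <- spec; spec1$item_loadings <- list(c(1), NULL, NULL)
  co3 <- simulate_items(co, spec1)
  expect_equal(co3$item_twin_9_1, as.numeric(scale(co$p_twin_9)),
               tolerance = 1e-12)
  # empty loadings: unchanged
  spec0 <- spec; spec0$item_loadings <- NULL
  expect_identical(simulate_items(co, spec0), co)
  specbad <- spec; specbad$item_loadings <- list(c(1.2), NULL, NULL)
  expect_error(simulate_items(co, specbad), "loadings")
})

test_that("missingness injection hits its rates and extremes", {
  spec <- default_genspec("twin", n_pairs = 10000L, seed = 3L,
                          miss_wave = c(0, 0, 0), attrition3 = 0.5)
  co <- simulate_cohort(spec)
  # all rates zero leaves the cohort untouched
  spec0 <- spec; spec0$attrition3 <- 0
  expect_identical(inject_missingness(co, spec0), co)
  # wave-3 attrition: pair-level fraction within 3 binomial SEs
  co3 <- inject_missingness(co, spec)
  lost <- tapply(is.na(co3$p_twin_16), co3$pair_id, all)
  expect_lt(abs(mean(lost) - 0.5), 3 * 0.5 / sqrt(spec$n_pairs))
  # cell rate 1 blanks a whole wave
  spec1 <- spec; spec1$attrition3 <- 0; spec1$miss_wave <- c(0, 1, 0)
  co2 <- inject_missingness(co, spec1)
  expect_true(all(is.na(co2$p_twin_12)))
  expect_true(all(is.na(co2$chaos_12)))
  expect_false(anyNA(co2$p_twin_9))
})

test_that("cohort seed streams are stage-independent", {
  spec <- default_genspec("twin", n_pairs = 300L, seed = 77L)
  co_a <- inject_missingness(simulate_cohort(spec), spec)
  # re-running only the missingness stage reproduces the same pattern
  co_b <- inject_missingness(simulate_cohort(spec), spec)
  expect_identical(co_a, co_b)
})
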