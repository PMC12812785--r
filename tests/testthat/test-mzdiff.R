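# MZ-differences design: cancellation of familial components and
# recovery of nonshared-environment dynamics.

test_that("difference scores cancel A and C exactly in noiseless data", {
  # A+C only: co-twins are identical, so all differences vanish
  spec <- diagonal_spec(0.6, 0.4, 0, b = 0.4, n_pairs = 500L, seed = 3L)
  spec$prop_mz <- 1
  spec$age_effect <- c(0, 0); spec$sex_effect <- c(0, 0)
  spec$chaos_disc_r <- 1  # no indicator-split noise: fully noiseless data
  co <- simulate_cohort(spec)
  co <- add_home_composite(co)
  dd <- mz_differences(co, seed = 1)
  num <- as.matrix(dd[, grep("^d_(p_twin|chaos|disc)", names(dd))])
  expect_lt(max(abs(num), na.rm = TRUE), 1e-10)
})

test_that("difference tables are seeded, MZ-only, and missing-aware", {
  spec <- default_genspec("twin", n_pairs = 500L, seed = 5L)
  co <- make_analysis_cohort(spec)
  d1 <- mz_differences(co, seed = 9)
  d2 <- mz_differences(co, seed = 9)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), sum(co$zygosity == "MZ") / 2)
  # difference missing iff either member missing
  mz <- co[co$zygosity == "MZ", ]
  miss_pair <- tapply(is.na(mz$p_twin_16), mz$pair_id, any)
  expect_identical(is.na(d1$d_p_twin_16),
                   as.vector(miss_pair[as.character(d1$pair_id)]))
  dzonly <- co[co$zygosity == "DZ", ]
  expect_error(mz_differences(dzonly, seed = 1), "MZ")
  desc <- attr(d1, "descriptives")
  expect_true(all(abs(desc$mean) < 3 * desc$sd / sqrt(desc$n)))
})

test_that("difference variance matches 2(1 - rMZ) under E-only truth", {
  spec <- single_component_spec("E", n_pairs = 20000L, seed = 6L)
  spec$prop_mz <- 1
  co <- simulate_cohort(spec)
  co <- add_home_composite(co)
  dd <- mz_differences(co, seed = 2)
  v <- stats::var(dd$d_p_twin_9, na.rm = TRUE)
  expect_lt(abs(v - 2), 3 * 2 * sqrt(2 / nrow(dd)))
})

test_that("difference correlations follow the E process", {
  spec <- single_component_spec("E", n_pairs = 10000L, seed = 7L)
  spec$prop_mz <- 1
  co <- simulate_cohort(spec)
  co <- add_home_composite(co)
  dd <- mz_differences(co, seed = 3)
  cm <- diff_correlations(dd)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  # implied lag-1 correlation of the E process (diagonal spec: b scaled)
  pe <- spec$processes$E
  implied <- twinclpm:::component_within_cov(pe)
  want <- stats::cov2cor(implied)[1, 3]
  expect_lt(abs(cm["d_p_twin_9", "d_p_twin_12"] - want), 3 / sqrt(nrow(dd)))
  # zero-stability process: lag correlations near zero
  spec0 <- single_component_spec("E", B12 = matrix(0, 2, 2),
                                 B23 = matrix(0, 2, 2), n_pairs = 10000L,
                                 seed = 8L)
  spec0$prop_mz <- 1
  co0 <- add_home_composite(simulate_cohort(spec0))
  cm0 <- diff_correlations(mz_differences(co0, seed = 4))
  expect_lt(abs(cm0["d_p_twin_9", "d_p_twin_12"]), 3 / sqrt(10000))
  expect_warning(diff_correlations(transform(dd, d_he_9 = 0)), "constant")
})

test_that("familial cross-lags vanish in the difference CLPM", {
  # large A and C cross-lags, zero E cross-lags
  Bac <- list(rbind(c(0.5, 0.2), c(0.25, 0.3)),
              rbind(c(0.5, 0.2), c(0.25, 0.3)))
  Be <- list(diag(c(0.3, 0.2)), diag(c(0.3, 0.2)))
  spec <- genspec_from_std(
    list(A = rbind(P = rep(0.4, 3), H = rep(0.3, 3)),
         C = rbind(P = rep(0.3, 3), H = rep(0.4, 3)),
         E = rbind(P = rep(0.3, 3), H = rep(0.3, 3))),
    B_std = list(A = Bac, C = Bac, E = Be), r_ph = 0.3,
    n_pairs = 5000L, prop_mz = 1, miss_wave = c(0, 0, 0), attrition3 = 0,
    seed = 9L)
  co <- make_analysis_cohort(spec)
  dd <- mz_differences(co, seed = 5)
  fit <- fit_diff_clpm(dd, n_boot = 300, seed = 5)
  cross <- fit$paths[fit$paths$path %in% c("P9->H12", "H9->P12"), ]
  halfwidth <- (cross$hi - cross$lo) / 2
  expect_true(all(abs(cross$std) < 3 * halfwidth / 1.96))
})

test_that("difference CLPM estimates the standardized E transitions", {
  Bt <- list(rbind(c(0.6, 0.05), c(0.12, 0.35)),
             rbind(c(0.6, 0.05), c(0.12, 0.35)))
  Be <- list(rbind(c(0.18, 0.02), c(0.09, 0.05)),
             rbind(c(0.18, 0.02), c(0.05, 0.08)))
  spec <- genspec_from_std(
    list(A = rbind(P = rep(0.45, 3), H = rep(0.2, 3)),
         C = rbind(P = rep(0.15, 3), H = rep(0.5, 3)),
         E = rbind(P = rep(0.4, 3), H = rep(0.3, 3))),
    B_std = list(A = Bt, C = Bt, E = Be), r_ph = 0.3,
    n_pairs = 5000L, prop_mz = 1, miss_wave = c(0, 0, 0), attrition3 = 0,
    seed = 10L)
  co <- make_analysis_cohort(spec)
  fit <- fit_diff_clpm(mz_differences(co, seed = 6), n_boot = 0)
  expect_lt(abs(fit$paths$std[fit$paths$path == "P9->H12"] - 0.09), 0.03)
  expect_lt(abs(fit$paths$std[fit$paths$path == "P9->P12"] - 0.18), 0.04)
})

test_that("difference CLPM equals the person-level CLPM under E-only truth", {
  spec <- single_component_spec("E", B12 = rbind(c(0.5, 0.1), c(0.2, 0.3)),
                                B23 = rbind(c(0.5, 0.1), c(0.2, 0.3)),
                                n_pairs = 20000L, seed = 11L)
  spec$prop_mz <- 1
  co <- add_home_composite(simulate_cohort(spec))
  cols <- twinclpm:::pair_columns("twin")
  person <- co[co$twin == 1, cols]
  names(person) <- twinclpm:::CLPM_VARS
  f_person <- fit_clpm(person)
  f_diff <- fit_diff_clpm(mz_differences(co, seed = 7), n_boot = 0)
  expect_lt(max(abs(f_person$paths$std[1:8] - f_diff$paths$std[1:8])), 0.05)
})
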