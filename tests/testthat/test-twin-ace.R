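# Twin correlations, Falconer arithmetic, univariate ACE and the
# biometric cross-lagged ACE model.

test_that("falconer estimates follow the closed forms", {
  f <- falconer_estimates(0.6, 0.35)
  expect_equal(c(f$a2, f$c2, f$e2), c(0.5, 0.1, 0.4))
  expect_false(f$out_of_bounds)
  f2 <- falconer_estimates(0.5, 0.5)
  expect_equal(c(f2$a2, f2$c2, f2$e2), c(0, 0.5, 0.5))
  f3 <- falconer_estimates(0.6, 0.2)
  expect_equal(c(f3$a2, f3$c2, f3$e2), c(0.8, -0.2, 0.4))
  expect_true(f3$out_of_bounds)
  expect_error(falconer_estimates(1.2, 0), "\\[-1, 1\\]")
})

test_that("twin correlations behave at the limits and under A-only truth", {
  spec <- default_genspec("twin", n_pairs = 400L, miss_wave = c(0, 0, 0),
                          attrition3 = 0, seed = 4L)
  co <- simulate_cohort(spec)
  ident <- co
  v <- ident[ident$twin == 1, "p_twin_9"]
  ident[ident$twin == 2, "p_twin_9"] <- v
  r <- twin_correlations(ident, "p_twin", 9)
  expect_equal(unname(r[["rMZ"]]), 1, tolerance = 1e-12)
  # independent co-twins: correlation near zero
  indep <- co
  indep[indep$twin == 2, "p_twin_9"] <- stats::rnorm(400)
  r0 <- twin_correlations(indep, "p_twin", 9)
  expect_lt(abs(r0[["rMZ"]]), 3 / sqrt(100))
  # A-only simulation: rMZ ~ a2, rDZ ~ a2/2
  pp <- simulate_ace_pairs(20000, 0.6, 0, seed = 5)
  co2 <- data.frame(pair_id = rep(pp$pair_id, 2),
                    zygosity = rep(pp$zygosity, 2),
                    twin = rep(1:2, each = nrow(pp)),
                    x_9 = c(pp$y1, pp$y2))
  r2 <- twin_correlations(co2, "x", 9)
  expect_lt(abs(r2[["rMZ"]] - 0.6), 3 / sqrt(sum(pp$zygosity == "MZ")))
  expect_lt(abs(r2[["rDZ"]] - 0.3), 3 / sqrt(sum(pp$zygosity == "DZ")))
  expect_error(twin_correlations(co[1:8, ], "p_twin", 9), "pairs")
})

test_that("univariate ACE recovers generating components with CIs", {
  # accuracy on a small fixed-seed battery (one draw has sd ~ 0.03)
  est <- sapply(1:3, function(s)
    unlist(fit_univariate_ace(simulate_ace_pairs(5000, 0.5, 0.2, seed = s),
                              n_boot = 0)[c("a2", "c2")]))
  expect_lt(abs(mean(est["a2", ]) - 0.5), 0.03)
  expect_lt(abs(mean(est["c2", ]) - 0.2), 0.03)
  pp <- simulate_ace_pairs(5000, 0.5, 0.2, seed = 6)
  fit <- fit_univariate_ace(pp, n_boot = 200, seed = 6)
  expect_equal(fit$a2 + fit$c2 + fit$e2, 1, tolerance = 1e-8)
  expect_true(all(fit$ci$lo <= c(fit$a2, fit$c2, fit$e2) + 1e-9))
  expect_true(all(fit$ci$hi >= c(fit$a2, fit$c2, fit$e2) - 1e-9))
  # submodel table: full model row has zero LRT against itself
  expect_equal(fit$submodels$LRT_chisq[1], 0)
  expect_true(all(diff(fit$submodels$k) <= 0))
})

test_that("E-only data prefer the E submodel and misspecification is punished", {
  pp <- simulate_ace_pairs(2000, 0, 0, seed = 8)
  cmp <- compare_submodels(pp)
  expect_lt(cmp$AIC[cmp$model == "E"], cmp$AIC[cmp$model == "ACE"])
  expect_gt(min(cmp$LRT_p, na.rm = TRUE), 0.001)
  # strong A signal: dropping A is rejected decisively
  pp2 <- simulate_ace_pairs(20000, 0.6, 0.1, seed = 9)
  cmp2 <- compare_submodels(pp2, family = c("CE"))
  expect_lt(cmp2$LRT_p[cmp2$model == "CE"], 1e-3)
  expect_error(compare_submodels(pp, family = "ADE"), "not nested")
})

test_that("FIML univariate ACE uses incomplete pairs", {
  pp <- simulate_ace_pairs(6000, 0.5, 0.2, seed = 10)
  pp$y2[sample(nrow(pp), 1500)] <- NA
  fit <- fit_univariate_ace(pp, n_boot = 0)
  expect_lt(abs(fit$a2 - 0.5), 0.06)
  expect_lt(abs(fit$c2 - 0.2), 0.06)
})

test_that("the biometric cross-lagged model recovers component dynamics", {
  spec <- default_genspec("twin", n_pairs = 6000L, miss_wave = c(0, 0, 0),
                          attrition3 = 0, seed = 12L)
  co <- make_analysis_cohort(spec)
  fit <- fit_crosslag_ace(co)
  expect_true(fit$converged)
  # component-level matrices are noisy at this n; sanity bounds here,
  # precise recovery is exercised at scale in the acceptance suite
  for (x in c("A", "C", "E")) {
    expect_lt(max(abs(fit$processes[[x]]$B12 - spec$processes[[x]]$B12)),
              0.35)
    expect_lt(max(abs(fit$processes[[x]]$sigma1 - spec$processes[[x]]$sigma1)),
              0.08)
  }
  # the phenotypic transition implied by the fit is tight
  dec_fit <- fit$decomposition
  dec_true <- decompose_paths(spec)
  expect_lt(max(abs(dec_fit$phenotypic - dec_true$phenotypic)), 0.05)
  # implied covariances reproduce the generating covariances
  for (z in c("MZ", "DZ")) {
    d <- build_expected_cov(spec, z) -
      twinclpm:::crosslag_implied(fit$processes, z)
    expect_lt(sqrt(mean(d^2)), 0.03)
  }
  # decomposition table invariants
  dec <- fit$decomposition
  expect_equal(dec$raw_A + dec$raw_C + dec$raw_E, dec$phenotypic,
               tolerance = 1e-10)
  expect_equal(dec$pA + dec$pC + dec$pE, rep(100, 8), tolerance = 1e-6)
})

test_that("twin-label swap leaves the pair likelihood unchanged", {
  spec <- default_genspec("twin", n_pairs = 300L, miss_wave = c(0, 0, 0),
                          attrition3 = 0, seed = 13L)
  co <- make_analysis_cohort(spec)
  mats <- twinclpm:::pair_matrix(co, "twin")
  mu <- rep(0, 12)
  sig <- build_expected_cov(spec, "MZ")
  ll1 <- twinclpm:::fiml_loglik(twinclpm:::fiml_patterns(mats$MZ), mu, sig)
  swapped <- mats$MZ[, c(7:12, 1:6)]
  ll2 <- twinclpm:::fiml_loglik(twinclpm:::fiml_patterns(swapped), mu, sig)
  expect_lt(abs(ll1 - ll2), 1e-8)
})

test_that("A-only generating spec yields near-zero fitted C and E dynamics", {
  spec <- single_component_spec("A", n_pairs = 6000L, seed = 14L)
  co <- make_analysis_cohort(spec)
  fit <- fit_crosslag_ace(co)
  # spurious C/E structure is bounded by sampling noise
  expect_lt(max(abs(fit$processes$C$sigma1)), 0.1)
  expect_lt(max(abs(fit$processes$E$sigma1)), 0.1)
  dec <- fit$decomposition
  expect_gt(min(dec$pA[c(1, 4)]), 75)  # stability paths dominated by A
})

test_that("decomposition handles single-component and symmetric cases", {
  # cross-lags present so every path is defined
  spec <- single_component_spec("C", B12 = rbind(c(0.6, 0.1), c(0.15, 0.4)),
                                B23 = rbind(c(0.5, 0.1), c(0.15, 0.3)))
  dec <- decompose_paths(spec)
  expect_equal(dec$pC, rep(100, 8))
  expect_equal(dec$pA + dec$pE, rep(0, 8))
  dspec <- diagonal_spec(1 / 3, 1 / 3, 1 / 3, b = 0.5)
  dec2 <- decompose_paths(dspec)
  expect_equal(dec2$pA[1], 100 / 3, tolerance = 1e-8)
  expect_equal(dec2$pC[4], 100 / 3, tolerance = 1e-8)
})

test_that("innovation variance shares track the generator", {
  dspec <- diagonal_spec(0.5, 0.2, 0.3, b = 0.5)
  # override wave-2 innovations to a known split
  for (x in c("A", "C", "E")) {
    v <- c(A = 0.2, C = 0.3, E = 0.5)[[x]]
    dspec$processes[[x]]$psi2 <- v * diag(2)
  }
  sh <- unique_variance(dspec)
  w2 <- sh[sh$wave == 12 & sh$trait == "P", ]
  expect_equal(c(w2$pA, w2$pC, w2$pE), c(20, 30, 50))
  expect_equal(rowSums(sh[, c("pA", "pC", "pE")]), rep(100, 6),
               tolerance = 1e-8)
  # zero innovations are flagged undefined
  for (x in c("A", "C", "E")) dspec$processes[[x]]$psi3 <- 0 * diag(2)
  sh0 <- unique_variance(dspec)
  expect_true(all(!sh0$defined[sh0$wave == 16]))
  expect_true(all(is.na(sh0$pA[sh0$wave == 16])))
})

test_that("solve_shares hits its targets and flags infeasibility", {
  dspec <- diagonal_spec(0.5, 0.3, 0.2, b = 0.5)
  # full-share target to a single component zeroes the others' paths
  s1 <- solve_shares(dspec, "P", "P", 1, c(1, 0, 0))
  expect_equal(s1$processes$C$B12[1, 1], 0, tolerance = 1e-10)
  expect_equal(s1$processes$E$B12[1, 1], 0, tolerance = 1e-10)
  d1 <- decompose_paths(s1)
  expect_equal(d1$pA[1], 100, tolerance = 1e-6)
  # equal shares with equal component variances give equal contributions
  eq <- diagonal_spec(1 / 3, 1 / 3, 1 / 3, b = 0.5)
  s2 <- solve_shares(eq, "H", "H", 2, c(1, 1, 1) / 3)
  d2 <- decompose_paths(s2)
  row <- d2[d2$path == "H12->H16", ]
  expect_equal(row$raw_A, row$raw_C, tolerance = 1e-10)
  expect_equal(row$raw_C, row$raw_E, tolerance = 1e-10)
  # published-style three-way target reproduces exactly
  base <- default_genspec("twin", n_pairs = 100L)
  s3 <- solve_shares(base, "P", "H", 2, c(0.54, 0.32, 0.14))
  d3 <- decompose_paths(s3)
  expect_equal(unlist(d3[d3$path == "P12->H16", c("pA", "pC", "pE")]),
               c(pA = 54, pC = 32, pE = 14), tolerance = 1e-6)
  # phenotypic magnitude is held at the base value
  b0 <- decompose_paths(base)
  expect_equal(d3$phenotypic[d3$path == "P12->H16"],
               b0$phenotypic[b0$path == "P12->H16"], tolerance = 1e-10)
  # infeasible: component with no variance cannot carry a share
  novar <- single_component_spec("A")
  expect_error(solve_shares(novar, "P", "P", 1, c(0.5, 0.5, 0)),
               "no variance|no signal")
  expect_error(solve_shares(dspec, "P", "P", 1, c(0.9, 0.3, -0.2)),
               "nonnegative")
})
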