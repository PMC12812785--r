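# Univariate ACE estimation and the biometric autoregressive cross-lagged
# ACE model.

# ---- pair-level data extraction ------------------------------------------

pair_columns <- function(rater) {
  p <- paste0("p_", rater, "_", WAVES)
  h <- paste0("he_", WAVES)
  c(p[1], h[1], p[2], h[2], p[3], h[3])
}

# n_pairs x 12 matrix (twin1 P9,H9,...,H16, then twin2) per zygosity group.
pair_matrix <- function(cohort, rater = attr(cohort, "rater") %||% "twin",
                        cols = pair_columns(rater)) {
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    stopf("cohort lacks columns: %s (run residualize/add_home_composite?)",
          paste(miss, collapse = ", "))
  t1 <- cohort[cohort$twin == 1, c("pair_id", "zygosity", cols)]
  t2 <- cohort[cohort$twin == 2, c("pair_id", cols)]
  m <- merge(t1, t2, by = "pair_id", suffixes = c("_t1", "_t2"))
  lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    sub <- m[m$zygosity == z, , drop = FALSE]
    as.matrix(sub[, c(paste0(cols, "_t1"), paste0(cols, "_t2"))])
  })
}

# ---- twin correlations and Falconer arithmetic ---------------------------

#' Double-entered twin correlations
#'
#' Pearson correlation between co-twins per zygosity group, with each pair
#' entered in both orderings so the estimate is symmetric in twin labels.
#'
#' @param cohort A `twin_cohort`.
#' @param trait Trait column stem (e.g. `"p_twin"`, `"he"`, `"chaos"`).
#' @param wave Wave age (9, 12 or 16).
#' @param min_pairs Minimum complete pairs per zygosity.
#' @return Named vector `c(rMZ =, rDZ =)`.
#' @export
twin_correlations <- function(cohort, trait, wave, min_pairs = 30L) {
  col <- paste0(trait, "_", wave)
  if (!col %in% names(cohort)) stopf("no column %s", col)
  t1 <- cohort[cohort$twin == 1, c("pair_id", "zygosity", col)]
  t2 <- cohort[cohort$twin == 2, c("pair_id", col)]
  m <- merge(t1, t2, by = "pair_id")
  out <- sapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    sub <- m[m$zygosity == z, , drop = FALSE]
    x <- sub[[3]]; y <- sub[[4]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs)
      stopf("fewer than %d complete %s pairs for %s", min_pairs, z, col)
    stats::cor(c(x[ok], y[ok]), c(y[ok], x[ok]))
  })
  names(out) <- c("rMZ", "rDZ")
  out
}

#' Falconer closed-form ACE estimates
#'
#' The textbook approximations from twin correlations: heritability is
#' twice the MZ-DZ correlation difference, shared environment is the MZ
#' correlation minus heritability, and nonshared environment (plus
#' measurement error) is one minus the MZ correlation.  Out-of-bound
#' components are flagged, not clamped.
#'
#' @param rMZ,rDZ Twin correlations in \[-1, 1\].
#' @return List with `a2`, `c2`, `e2` and logical `out_of_bounds`.
#' @export
falconer_estimates <- function(rMZ, rDZ) {
  if (abs(rMZ) > 1 || abs(rDZ) > 1) stopf("correlations must lie in [-1, 1]")
  a2 <- 2 * (rMZ - rDZ)
  c2 <- rMZ - a2
  e2 <- 1 - rMZ
  list(a2 = a2, c2 = c2, e2 = e2,
       out_of_bounds = any(c(a2, c2, e2) < 0 | c(a2, c2, e2) > 1))
}

# ---- univariate ACE ------------------------------------------------------

ace_pair_patterns <- function(y1, y2) {
  Y <- cbind(y1, y2)
  fiml_patterns(Y)
}

ace_loglik <- function(pats_mz, pats_dz, mu, a, c_, e) {
  v <- a^2 + c_^2 + e^2
  sig <- function(r) matrix(c(v, r * a^2 + c_^2, r * a^2 + c_^2, v), 2, 2)
  fiml_loglik(pats_mz, c(mu, mu), sig(1)) +
    fiml_loglik(pats_dz, c(mu, mu), sig(0.5))
}

fit_ace_core <- function(pats_mz, pats_dz, model = "ACE") {
  free <- list(ACE = c(TRUE, TRUE, TRUE), AE = c(TRUE, FALSE, TRUE),
               CE = c(FALSE, TRUE, TRUE), E = c(FALSE, FALSE, TRUE))[[model]]
  if (is.null(free)) stopf("unknown submodel %s", model)
  obj <- function(par) {
    full <- c(0, 0, 0)
    full[free] <- par[-1]
    ace_loglik(pats_mz, pats_dz, par[1], full[1], full[2], full[3])
  }
  start <- c(0, rep(sqrt(1 / sum(free)), sum(free)))
  best <- fiml_maximize(start, obj, restarts = 3L)
  full <- c(0, 0, 0); full[free] <- abs(best$par[-1])
  v <- sum(full^2)
  list(mu = best$par[1], a = full[1], c = full[2], e = full[3],
       a2 = full[1]^2 / v, c2 = full[2]^2 / v, e2 = full[3]^2 / v,
       loglik = best$value, k = 1L + sum(free),
       converged = best$convergence == 0)
}

extract_pairs <- function(cohort, trait, wave) {
  if (all(c("y1", "y2") %in% names(cohort)))
    return(cohort[, c("zygosity", "y1", "y2")])
  col <- paste0(trait, "_", wave)
  if (!col %in% names(cohort)) stopf("no column %s", col)
  t1 <- cohort[cohort$twin == 1, c("pair_id", "zygosity", col)]
  t2 <- cohort[cohort$twin == 2, c("pair_id", col)]
  m <- merge(t1, t2, by = "pair_id")
  data.frame(zygosity = m$zygosity, y1 = m[[3]], y2 = m[[4]])
}

#' Univariate ACE model by FIML
#'
#' Maximum likelihood over the 2x2 expected twin-pair covariances
#' (variance `a2 + c2 + e2`; cross-twin covariance `a2 r_A + c2` with
#' r_A = 1 for MZ and 0.5 for DZ), casewise over incomplete pairs.
#' Confidence intervals by pair-level percentile bootstrap; AE/CE/E
#' submodels compared to the full model by likelihood-ratio test and AIC.
#'
#' @param cohort A `twin_cohort`, or a pair table with columns `zygosity`,
#'   `y1`, `y2` (e.g. from [simulate_ace_pairs()]).
#' @param trait,wave Trait column stem and wave (ignored for pair tables).
#' @param n_boot Bootstrap draws for the CIs (0 skips them).
#' @param seed Bootstrap seed.
#' @return An `ace_fit`: `a2`, `c2`, `e2`, `ci` (when bootstrapped),
#'   `rMZ`, `rDZ`, `submodels` comparison table, `loglik`, `n_pairs`.
#' @export
fit_univariate_ace <- function(cohort, trait = NULL, wave = NULL,
                               n_boot = 500L, seed = 1L) {
  pairs <- extract_pairs(cohort, trait, wave)
  if (!all(c("MZ", "DZ") %in% pairs$zygosity))
    stopf("both zygosity groups are required")
  mz <- pairs[pairs$zygosity == "MZ", ]
  dz <- pairs[pairs$zygosity == "DZ", ]
  pats_mz <- ace_pair_patterns(mz$y1, mz$y2)
  pats_dz <- ace_pair_patterns(dz$y1, dz$y2)
  full <- fit_ace_core(pats_mz, pats_dz, "ACE")
  if (!full$converged) stopf("univariate ACE fit did not converge")
  subs <- lapply(c(AE = "AE", CE = "CE", E = "E"), function(mm)
    fit_ace_core(pats_mz, pats_dz, mm))
  cmp <- data.frame(
    model = c("ACE", names(subs)),
    minus2LL = -2 * c(full$loglik, sapply(subs, `[[`, "loglik")),
    k = c(full$k, sapply(subs, `[[`, "k")))
  cmp$AIC <- cmp$minus2LL + 2 * cmp$k
  cmp$LRT_chisq <- cmp$minus2LL - cmp$minus2LL[1]
  cmp$LRT_df <- cmp$k[1] - cmp$k
  cmp$LRT_p <- ifelse(cmp$LRT_df > 0,
                      stats::pchisq(cmp$LRT_chisq, cmp$LRT_df,
                                    lower.tail = FALSE), NA)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    draws <- matrix(NA_real_, n_boot, 3L)
    n <- nrow(pairs)
    for (b in seq_len(n_boot)) {
      rs <- pairs[sample.int(n, n, replace = TRUE), ]
      mzb <- rs[rs$zygosity == "MZ", ]; dzb <- rs[rs$zygosity == "DZ", ]
      fb <- tryCatch(
        fit_ace_core(ace_pair_patterns(mzb$y1, mzb$y2),
                     ace_pair_patterns(dzb$y1, dzb$y2), "ACE"),
        error = function(e) NULL)
      if (!is.null(fb)) draws[b, ] <- c(fb$a2, fb$c2, fb$e2)
    }
    qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci <- data.frame(component = c("a2", "c2", "e2"),
                     lo = qs[1, ], hi = qs[2, ])
  }
  rr <- tryCatch({
    de <- function(d) stats::cor(c(d$y1, d$y2), c(d$y2, d$y1),
                                 use = "complete.obs")
    c(rMZ = de(mz), rDZ = de(dz))
  }, error = function(e) c(rMZ = NA, rDZ = NA))
  structure(
    list(a2 = full$a2, c2 = full$c2, e2 = full$e2, mu = full$mu,
         ci = ci, rMZ = rr[["rMZ"]], rDZ = rr[["rDZ"]], submodels = cmp,
         loglik = full$loglik, n_pairs = c(MZ = nrow(mz), DZ = nrow(dz))),
    class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("Univariate ACE (MZ %d / DZ %d pairs)\n",
              x$n_pairs["MZ"], x$n_pairs["DZ"]))
  cat(sprintf("  a2 = %.3f, c2 = %.3f, e2 = %.3f (rMZ %.3f, rDZ %.3f)\n",
              x$a2, x$c2, x$e2, x$rMZ, x$rDZ))
  invisible(x)
}

#' Compare nested ACE submodels
#'
#' Fits the requested constrained submodels of the univariate ACE model
#' and reports -2 log-likelihood, parameter counts, AIC, and the
#' likelihood-ratio test of each against the full model.
#'
#' @param cohort,trait,wave As for [fit_univariate_ace()].
#' @param family Submodels to fit, from `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @return The comparison data.frame.
#' @export
compare_submodels <- function(cohort, trait = NULL, wave = NULL,
                              family = c("AE", "CE", "E")) {
  bad <- setdiff(family, c("ACE", "AE", "CE", "E"))
  if (length(bad))
    stopf("not nested in the ACE model: %s", paste(bad, collapse = ", "))
  fit <- fit_univariate_ace(cohort, trait, wave, n_boot = 0)
  fit$submodels[fit$submodels$model %in% c("ACE", family), ]
}

# ---- biometric cross-lagged ACE model ------------------------------------

proc_from_raw <- function(x, sigma1, B12, psi2, B23, psi3) {
  list(component = x, sigma1 = symm(sigma1), B12 = B12, B23 = B23,
       psi2 = symm(psi2), psi3 = symm(psi3))
}

# 17 parameters per component: chol(sigma1), B12, chol(psi2), B23, chol(psi3)
pack_proc <- function(p) {
  safe_chol <- function(m) t(chol(psd_project(m, 1e-8) + 1e-9 * diag(2)))
  c(vech_lower(safe_chol(p$sigma1)), as.numeric(p$B12),
    vech_lower(safe_chol(p$psi2)), as.numeric(p$B23),
    vech_lower(safe_chol(p$psi3)))
}

unpack_proc <- function(par, x) {
  proc_from_raw(x,
                tcrossprod(unvech_lower(par[1:3], 2)),
                matrix(par[4:7], 2, 2),
                tcrossprod(unvech_lower(par[8:10], 2)),
                matrix(par[11:14], 2, 2),
                tcrossprod(unvech_lower(par[15:17], 2)))
}

crosslag_implied <- function(procs, zygosity) {
  within <- matrix(0, 6, 6); cross <- matrix(0, 6, 6)
  for (x in c("A", "C", "E")) {
    w <- component_within_cov(procs[[x]])
    within <- within + w
    cross <- cross + twin_corr_factor(x, zygosity) * w
  }
  rbind(cbind(within, cross), cbind(t(cross), within))
}

# Moment-based starting values: decompose the empirical within/cross-twin
# blocks into per-component 6x6 covariances, then read the process
# parameters off each by the recursive factorization.
crosslag_start <- function(Ymz, Ydz) {
  swap <- c(7:12, 1:6)
  emp <- function(Y) {
    S <- pairwise_moments(Y)$S
    symm((S + S[swap, swap]) / 2)
  }
  Smz <- emp(Ymz); Sdz <- emp(Ydz)
  nmz <- nrow(Ymz); ndz <- nrow(Ydz)
  W <- (nmz * (Smz[1:6, 1:6] + Smz[7:12, 7:12]) / 2 +
          ndz * (Sdz[1:6, 1:6] + Sdz[7:12, 7:12]) / 2) / (nmz + ndz)
  xmz <- symm((Smz[1:6, 7:12] + t(Smz[1:6, 7:12])) / 2)
  xdz <- symm((Sdz[1:6, 7:12] + t(Sdz[1:6, 7:12])) / 2)
  comp6 <- list(A = psd_project(2 * (xmz - xdz), 1e-4),
                C = psd_project(2 * xdz - xmz, 1e-4),
                E = psd_project(W - xmz, 1e-4))
  lapply(names(comp6), function(x) {
    S <- comp6[[x]]
    th <- clpm_from_cov(S + 1e-6 * diag(6))
    proc_from_raw(x, th$sigma1, th$B12, psd_project(th$psi2, 1e-6),
                  th$B23, psd_project(th$psi3, 1e-6))
  }) |> stats::setNames(c("A", "C", "E"))
}

#' Biometric autoregressive cross-lagged ACE model
#'
#' Fits the component-level cross-lagged twin model: each of the A, C and
#' E components of the bivariate \[p, home-environment\] process has its
#' own wave-1 covariance, transition matrices and innovation covariances,
#' and the zygosity contrast in the cross-twin, cross-trait covariances
#' identifies the split.  The summed casewise Gaussian log-likelihood over
#' MZ and DZ pairs of the 12-dimensional pair observation is maximized
#' with covariance matrices kept PSD via Cholesky-factor parameterization;
#' starting values come from a moment decomposition of the empirical
#' within- and cross-twin blocks.
#'
#' @param cohort A residualized `twin_cohort` with home-composite columns
#'   (see [residualize_age_sex()] and [add_home_composite()]).
#' @param rater Which rater's p score to analyse.
#' @param restarts Jittered optimizer restarts.
#' @return A `biometric_fit`: `processes` (per-component matrices),
#'   `decomposition` ([decompose_paths()] table), `innovation_shares`
#'   ([unique_variance()]), `fit` (pooled [model_fit_stats()] row),
#'   `loglik`, `n_pairs`, `converged`.
#' @export
fit_crosslag_ace <- function(cohort, rater = attr(cohort, "rater") %||% "twin",
                             restarts = 5L) {
  mats <- pair_matrix(cohort, rater)
  Ymz <- mats$MZ; Ydz <- mats$DZ
  if (nrow(Ymz) < 30 || nrow(Ydz) < 30)
    stopf("need at least 30 pairs per zygosity")
  pats_mz <- fiml_patterns(Ymz)
  pats_dz <- fiml_patterns(Ydz)
  mu0 <- colMeans(rbind(Ymz, Ydz), na.rm = TRUE)
  mu0 <- (mu0[1:6] + mu0[7:12]) / 2
  start_procs <- crosslag_start(Ymz, Ydz)
  par0 <- c(mu0, unlist(lapply(start_procs, pack_proc), use.names = FALSE))
  unpack <- function(par) {
    list(mu = par[1:6],
         procs = list(A = unpack_proc(par[6 + 1:17], "A"),
                      C = unpack_proc(par[23 + 1:17], "C"),
                      E = unpack_proc(par[40 + 1:17], "E")))
  }
  obj <- function(par) {
    q <- unpack(par)
    mu12 <- rep(q$mu, 2)
    fiml_loglik(pats_mz, mu12, crosslag_implied(q$procs, "MZ")) +
      fiml_loglik(pats_dz, mu12, crosslag_implied(q$procs, "DZ"))
  }
  best <- fiml_maximize(par0, obj, restarts = restarts, jitter_sd = 0.02)
  q <- unpack(best$par)
  if (best$convergence != 0)
    warning("cross-lagged ACE optimizer hit the iteration limit; ",
            "returning the best-found parameters", call. = FALSE)
  procs <- lapply(q$procs, function(p)
    component_process(p$component, p$sigma1, p$B12, p$B23, p$psi2, p$psi3))
  # pooled fit statistics vs the (approximate under missingness) empirical
  # per-zygosity moments; df = 2 * 78 moments - 51 structure parameters
  fit <- tryCatch({
    fml <- function(Y, z) {
      S <- pairwise_moments(Y)$S
      Sig <- crosslag_implied(q$procs, z)
      n <- nrow(Y)
      ms <- model_fit_stats(S, Sig, n, df_model = 0)
      c(chisq = ms$chi_square, ll = ms$loglik, n = n)
    }
    g1 <- fml(Ymz, "MZ"); g2 <- fml(Ydz, "DZ")
    chisq <- g1[["chisq"]] + g2[["chisq"]]
    df <- 2 * 78 - 51
    n <- g1[["n"]] + g2[["n"]]
    data.frame(chi_square = chisq, df = df,
               RMSEA = sqrt(max(chisq - df, 0) / (df * (n - 1))),
               loglik = best$value,
               AIC = -2 * best$value + 2 * 57,
               BIC = -2 * best$value + log(n) * 57)
  }, error = function(e) NULL)
  out <- structure(
    list(processes = procs, means = q$mu, loglik = best$value,
         fit = fit, n_pairs = c(MZ = nrow(Ymz), DZ = nrow(Ydz)),
         converged = best$convergence == 0),
    class = "biometric_fit")
  out$decomposition <- decompose_paths(out)
  out$innovation_shares <- unique_variance(out)
  out
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("Biometric cross-lagged ACE model (MZ %d / DZ %d pairs)\n",
              x$n_pairs["MZ"], x$n_pairs["DZ"]))
  tab <- x$decomposition
  tab[c("pA", "pC", "pE")] <- round(tab[c("pA", "pC", "pE")], 1)
  tab$phenotypic <- round(tab$phenotypic, 3)
  print(tab[, c("path", "phenotypic", "pA", "pC", "pE")], row.names = FALSE)
  invisible(x)
}
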