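#' Latent component process for one variance component
#'
#' A `component_process` describes how one biometric variance component
#' (additive genetic A, shared environment C, or nonshared environment E)
#' of the bivariate trait vector \[P, H\] (psychopathology factor, home
#' environment) evolves over the three measurement waves: its wave-1
#' covariance, the 2x2 transition matrices linking consecutive waves
#' (rows index the outcome trait at the later wave, columns the predictor
#' trait at the earlier wave), and the innovation covariances at waves 2
#' and 3.
#'
#' @param component One of `"A"`, `"C"`, `"E"`.
#' @param sigma1 2x2 symmetric PSD covariance of the component at wave 1.
#' @param B12,B23 2x2 transition matrices (wave 1 to 2 and wave 2 to 3).
#' @param psi2,psi3 2x2 symmetric PSD innovation covariances at waves 2, 3.
#' @return An object of class `component_process`.
#' @export
component_process <- function(component, sigma1, B12, B23, psi2, psi3) {
  component <- match.arg(component, c("A", "C", "E"))
  for (nm in c("sigma1", "B12", "B23", "psi2", "psi3")) {
    m <- get(nm)
    if (!is.matrix(m) || !all(dim(m) == c(2L, 2L)))
      stopf("%s must be a 2x2 matrix", nm)
  }
  for (nm in c("sigma1", "psi2", "psi3")) {
    if (!is_symmetric_psd(get(nm)))
      stopf("%s for component %s is not symmetric positive semi-definite",
            nm, component)
  }
  structure(
    list(component = component, sigma1 = unname(symm(sigma1)),
         B12 = unname(B12), B23 = unname(B23),
         psi2 = unname(symm(psi2)), psi3 = unname(symm(psi3))),
    class = "component_process")
}

#' Full generating model for a synthetic twin cohort
#'
#' Bundles one [component_process()] per A/C/E component with the cohort
#' demographics, observation-layer effects and missingness settings needed
#' to simulate a three-wave twin study with known ground truth.
#'
#' @param processes Named list with elements `A`, `C`, `E`, each a
#'   [component_process()].
#' @param n_pairs Number of twin pairs.
#' @param prop_mz Proportion of monozygotic pairs, in \[0, 1\].
#' @param prop_female Proportion of female twins, in \[0, 1\].
#' @param age_means,age_sds Length-3 vectors: mean and SD of age (years) at
#'   each wave. Twins in a pair share their age.
#' @param age_effect,sex_effect Length-2 vectors (traits \[P, H\]): linear
#'   slope on age (per year, centred at the wave mean) and on the 0/1
#'   female indicator added to the observed scores.
#' @param chaos_disc_r Correlation between the two home-environment
#'   indicators (household chaos and parental discipline) that split the
#'   latent H trait.
#' @param item_loadings Optional list of numeric loading vectors (one per
#'   wave, values in (0, 1\]) used by [simulate_items()].
#' @param miss_wave Length-3 vector of per-wave missing-completely-at-random
#'   cell rates.
#' @param attrition3 Fraction of pairs losing all wave-3 observations
#'   (emulating a study wave administered to only part of the cohort).
#' @param seed Integer seed; all simulation draws stream from it.
#' @return An object of class `genspec`.
#' @seealso [default_genspec()], [genspec_from_std()], [simulate_cohort()]
#' @export
gen_spec <- function(processes, n_pairs = 6212L, prop_mz = 0.344,
                     prop_female = 0.509,
                     age_means = c(9.02, 11.31, 16.32),
                     age_sds = c(0.29, 0.72, 0.68),
                     age_effect = c(0.05, 0.05),
                     sex_effect = c(0.2, 0.2),
                     chaos_disc_r = 0.3,
                     item_loadings = NULL,
                     miss_wave = c(0, 0, 0),
                     attrition3 = 0,
                     seed = 1L) {
  if (!is.list(processes) || !setequal(names(processes), c("A", "C", "E")))
    stopf("processes must be a named list with components A, C and E")
  for (x in c("A", "C", "E")) {
    if (!inherits(processes[[x]], "component_process"))
      stopf("processes$%s must be a component_process", x)
    if (processes[[x]]$component != x)
      stopf("processes$%s is labelled %s", x, processes[[x]]$component)
  }
  if (length(n_pairs) != 1L || n_pairs <= 0)
    stopf("n_pairs must be a positive integer")
  for (nm in c("prop_mz", "prop_female")) {
    v <- get(nm)
    if (v < 0 || v > 1) stopf("%s must lie in [0, 1]", nm)
  }
  if (any(miss_wave < 0 | miss_wave > 1) || attrition3 < 0 || attrition3 > 1)
    stopf("missingness rates must lie in [0, 1]")
  if (!is.null(item_loadings)) {
    for (lam in item_loadings)
      if (any(lam <= 0 | lam > 1)) stopf("item loadings must lie in (0, 1]")
  }
  if (abs(chaos_disc_r) > 1) stopf("chaos_disc_r must lie in [-1, 1]")
  structure(
    list(processes = processes[c("A", "C", "E")],
         n_pairs = as.integer(n_pairs), prop_mz = prop_mz,
         prop_female = prop_female, age_means = age_means, age_sds = age_sds,
         age_effect = age_effect, sex_effect = sex_effect,
         chaos_disc_r = chaos_disc_r, item_loadings = item_loadings,
         miss_wave = miss_wave, attrition3 = attrition3,
         seed = as.integer(seed)),
    class = "genspec")
}

#' @export
print.genspec <- function(x, ...) {
  cat("Twin-cohort generating model (genspec)\n")
  cat(sprintf("  pairs: %d (MZ %.1f%%, female %.1f%%)\n",
              x$n_pairs, 100 * x$prop_mz, 100 * x$prop_female))
  v1 <- sapply(x$processes, function(p) diag(p$sigma1))
  cat("  wave-1 variance components (rows P, H):\n")
  print(round(v1, 3))
  cat(sprintf("  MCAR cell rates: %s; wave-3 attrition: %.2f\n",
              paste(x$miss_wave, collapse = "/"), x$attrition3))
  invisible(x)
}

# Build target per-component covariance matrices at one wave from variance
# fractions and a phenotypic cross-trait correlation.  The cross-trait
# covariance is split across components with a common component-level
# correlation r* chosen so the components sum to the phenotypic matrix.
component_wave_cov <- function(fracs, r_ph) {
  # fracs: named list A/C/E of c(vP, vH) variance fractions at this wave
  s <- sum(sapply(fracs, function(v) sqrt(v[1] * v[2])))
  if (s <= 0) stopf("all component variances are zero at a wave")
  rstar <- r_ph / s
  if (abs(rstar) > 1)
    stopf("cross-trait correlation %.2f infeasible for these fractions", r_ph)
  lapply(fracs, function(v) {
    cv <- rstar * sqrt(v[1] * v[2])
    matrix(c(v[1], cv, cv, v[2]), 2, 2)
  })
}

#' Build a generating model from standardized component dynamics
#'
#' Constructs a [gen_spec()] whose per-wave, per-trait variance fractions
#' and per-component standardized transition matrices are stated directly.
#' The phenotypic variance of each trait is 1 at every wave; the cross-trait
#' phenotypic correlation `r_ph` is split across components with a common
#' component-level correlation.  Raw transitions are recovered from the
#' standardized ones via the implied component SDs, and innovation
#' covariances are set to top the component covariance up to its per-wave
#' target (an error is raised if that innovation matrix is not PSD, i.e.
#' the requested dynamics are infeasible).
#'
#' @param fractions Named list `A`/`C`/`E`; each a 2x3 matrix of variance
#'   fractions (rows traits \[P, H\], columns waves). Columns of the three
#'   matrices must sum to 1 per trait.
#' @param B_std Named list `A`/`C`/`E`; each a list of two 2x2 standardized
#'   transition matrices (waves 1-2 and 2-3), rows = outcome trait.
#' @param r_ph Phenotypic cross-trait correlation per wave (scalar or
#'   length-3).
#' @param ... Passed on to [gen_spec()] (demographics, missingness, seed).
#' @return A `genspec`.
#' @export
genspec_from_std <- function(fractions, B_std, r_ph = 0.3, ...) {
  if (length(r_ph) == 1L) r_ph <- rep(r_ph, 3L)
  fr_wave <- function(w) lapply(fractions, function(m) m[, w])
  tot <- Reduce(`+`, fractions)
  if (max(abs(tot - 1)) > 1e-8)
    stopf("component variance fractions must sum to 1 per trait per wave")
  covs <- lapply(1:3, function(w) component_wave_cov(fr_wave(w), r_ph[w]))
  procs <- list()
  for (x in c("A", "C", "E")) {
    sig <- lapply(covs, `[[`, x)
    raw_B <- function(t) {
      sd_from <- sqrt(pmax(diag(sig[[t]]), 0))
      sd_to <- sqrt(pmax(diag(sig[[t + 1]]), 0))
      Bs <- B_std[[x]][[t]]
      B <- Bs * outer(sd_to, 1 / pmax(sd_from, 1e-12))
      B[, sd_from <= 0] <- 0
      B
    }
    B12 <- raw_B(1); B23 <- raw_B(2)
    psi2 <- symm(sig[[2]] - B12 %*% sig[[1]] %*% t(B12))
    psi3 <- symm(sig[[3]] - B23 %*% sig[[2]] %*% t(B23))
    for (ps in list(psi2, psi3)) {
      if (min(eigen(ps, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        stopf("component %s: requested dynamics imply a non-PSD innovation", x)
    }
    procs[[x]] <- component_process(x, sig[[1]], B12, B23,
                                    psd_project(psi2), psd_project(psi3))
  }
  gen_spec(procs, ...)
}

# Default per-wave variance-component fractions (rows P, H traits are built
# separately).  These calibrate the generator to a large UK child twin
# cohort: parent-rated p is strongly heritable, child-rated p moderately so
# with a large nonshared component, and the child-rated home environment is
# dominated by the shared environment.
default_fractions <- function(rater = c("twin", "parent")) {
  rater <- match.arg(rater)
  if (rater == "parent") {
    a_p <- c(0.51, 0.67, 0.59); c_p <- c(0.10, 0.08, 0.10)
  } else {
    a_p <- c(0.47, 0.42, 0.46); c_p <- c(0.13, 0.18, 0.14)
  }
  a_h <- c(0.19, 0.19, 0.31); c_h <- c(0.55, 0.55, 0.45)
  list(A = rbind(P = a_p, H = a_h),
       C = rbind(P = c_p, H = c_h),
       E = rbind(P = 1 - a_p - c_p, H = 1 - a_h - c_h))
}

# Default standardized phenotypic-scale transitions: strong p stability,
# weaker home-environment stability, small bidirectional cross-lags.
default_transitions <- function(rater = c("twin", "parent")) {
  rater <- match.arg(rater)
  if (rater == "parent") {
    B1 <- rbind(P = c(0.70, 0.04), H = c(0.18, 0.40))
    B2 <- rbind(P = c(0.70, 0.08), H = c(0.10, 0.40))
  } else {
    B1 <- rbind(P = c(0.70, 0.11), H = c(0.14, 0.40))
    B2 <- rbind(P = c(0.70, 0.02), H = c(0.13, 0.40))
  }
  colnames(B1) <- colnames(B2) <- c("P", "H")
  list(B1, B2)
}

#' Default cohort-emulation generating model
#'
#' A calibrated [gen_spec()] emulating a large three-wave UK twin study of
#' child psychopathology and child-rated home environment: 6,212 pairs,
#' 34.4% MZ, 50.9% female, waves at ages 9/12/16, half the pairs missing
#' wave 3, chaos-discipline correlation .3, strongly heritable p, and a
#' shared-environment-dominated home composite.  All three components share
#' the phenotypic standardized transition matrices, so the implied A/C/E
#' path shares follow the variance fractions; use [solve_shares()] to
#' retarget individual paths.
#'
#' @param rater `"twin"` or `"parent"` — which rater's p-factor dynamics to
#'   emulate (the home-environment trait is twin-rated in both).
#' @param ... Overrides passed to [gen_spec()].
#' @return A `genspec`.
#' @export
default_genspec <- function(rater = c("twin", "parent"), ...) {
  rater <- match.arg(rater)
  Bp <- default_transitions(rater)
  args <- list(...)
  if (!"miss_wave" %in% names(args)) args$miss_wave <- c(0.05, 0.05, 0.05)
  if (!"attrition3" %in% names(args)) args$attrition3 <- 0.5
  do.call(genspec_from_std,
          c(list(fractions = default_fractions(rater),
                 B_std = list(A = Bp, C = Bp, E = Bp),
                 r_ph = 0.3),
            args))
}
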