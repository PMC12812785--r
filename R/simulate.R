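# Synthetic twin-cohort simulation with known component-level ground truth.

# Draw one component's three-wave trajectories for both twins of n pairs.
# Cross-twin correlation r is induced at the innovation level:
# zeta_twin = sqrt(r) * common + sqrt(1 - r) * unique, which keeps the
# marginal covariance exact and handles r = 1 (perfect sharing) without a
# singular joint covariance.
simulate_component <- function(p, n, r) {
  draw <- function(cov2) {
    L <- t(mat_sqrt(cov2))
    matrix(stats::rnorm(n * 2), n, 2) %*% L
  }
  shared_draw <- function(cov2) {
    g0 <- draw(cov2); g1 <- draw(cov2); g2 <- draw(cov2)
    a <- sqrt(r); b <- sqrt(1 - r)
    list(a * g0 + b * g1, a * g0 + b * g2)
  }
  x1 <- shared_draw(p$sigma1)
  z2 <- shared_draw(p$psi2)
  z3 <- shared_draw(p$psi3)
  lapply(1:2, function(j) {
    w1 <- x1[[j]]
    w2 <- w1 %*% t(p$B12) + z2[[j]]
    w3 <- w2 %*% t(p$B23) + z3[[j]]
    cbind(w1, w2, w3)  # columns P9 H9 P12 H12 P16 H16
  })
}

trait_cols <- function(rater) {
  c(paste0("p_", rater, "_", WAVES), paste0("chaos_", WAVES),
    paste0("disc_", WAVES))
}

#' Simulate a twin cohort from a generating model
#'
#' Draws `n_pairs` twin pairs from the zero-mean Gaussian process implied
#' by the spec (zygosity-appropriate cross-twin structure), adds linear
#' age and sex effects to the observed scores, splits the latent home
#' trait into chaos and discipline indicators correlating at
#' `spec$chaos_disc_r`, and assigns demographics at the specified
#' proportions.  Deterministic given `spec$seed`; the seed streams to the
#' draw stages in fixed order (demographics, latent trajectories, ages,
#' indicator split), so e.g. [inject_missingness()] can be re-run without
#' changing the underlying scores.
#'
#' @param spec A [gen_spec()].
#' @param rater `"twin"` or `"parent"`: which rater's p-score columns the
#'   simulated P trait is written to.
#' @return A `twin_cohort` data.frame, two rows per pair, with columns
#'   `pair_id`, `zygosity`, `twin`, `sex`, `age_<wave>`,
#'   `p_<rater>_<wave>`, `chaos_<wave>`, `disc_<wave>`.
#' @export
simulate_cohort <- function(spec, rater = c("twin", "parent")) {
  rater <- match.arg(rater)
  if (!inherits(spec, "genspec")) stopf("spec must be a genspec")
  n <- spec$n_pairs
  if (n <= 0) stopf("n_pairs must be positive")

  set.seed(sub_seed(spec$seed, 1L))  # stage 1: demographics
  zyg <- ifelse(stats::runif(n) < spec$prop_mz, "MZ", "DZ")
  sex1 <- ifelse(stats::runif(n) < spec$prop_female, "F", "M")
  # MZ co-twins share sex; DZ co-twins are drawn independently
  sex2 <- ifelse(zyg == "MZ", sex1,
                 ifelse(stats::runif(n) < spec$prop_female, "F", "M"))

  set.seed(sub_seed(spec$seed, 2L))  # stage 2: latent trajectories
  lat <- list(matrix(0, n, 6), matrix(0, n, 6))
  for (z in c("MZ", "DZ")) {
    idx <- which(zyg == z)
    if (!length(idx)) next
    acc <- list(matrix(0, length(idx), 6), matrix(0, length(idx), 6))
    for (x in c("A", "C", "E")) {
      r <- twin_corr_factor(x, z)
      comp <- simulate_component(spec$processes[[x]], length(idx), r)
      acc[[1]] <- acc[[1]] + comp[[1]]
      acc[[2]] <- acc[[2]] + comp[[2]]
    }
    lat[[1]][idx, ] <- acc[[1]]
    lat[[2]][idx, ] <- acc[[2]]
  }

  set.seed(sub_seed(spec$seed, 3L))  # stage 3: ages (shared within pair)
  ages <- sapply(1:3, function(w)
    stats::rnorm(n, spec$age_means[w], spec$age_sds[w]))

  set.seed(sub_seed(spec$seed, 4L))  # stage 4: chaos/discipline split
  alpha <- sqrt((1 + spec$chaos_disc_r) / 2)
  beta <- sqrt((1 - spec$chaos_disc_r) / 2)
  rows <- vector("list", 2L)
  for (j in 1:2) {
    sexj <- if (j == 1) sex1 else sex2
    sex01 <- as.numeric(sexj == "F")
    P <- lat[[j]][, c(1, 3, 5)]
    H <- lat[[j]][, c(2, 4, 6)]
    age_c <- sweep(ages, 2, spec$age_means)
    Pobs <- P + spec$age_effect[1] * age_c + spec$sex_effect[1] * sex01
    Hobs <- H + spec$age_effect[2] * age_c + spec$sex_effect[2] * sex01
    d <- matrix(stats::rnorm(n * 3), n, 3)
    chaos <- alpha * Hobs + beta * d
    disc <- alpha * Hobs - beta * d
    df <- data.frame(pair_id = seq_len(n), zygosity = zyg, twin = j,
                     sex = sexj,
                     age_9 = ages[, 1], age_12 = ages[, 2], age_16 = ages[, 3])
    df[paste0("p_", rater, "_", WAVES)] <- as.data.frame(Pobs)
    df[paste0("chaos_", WAVES)] <- as.data.frame(chaos)
    df[paste0("disc_", WAVES)] <- as.data.frame(disc)
    rows[[j]] <- df
  }
  out <- rbind(rows[[1]], rows[[2]])
  out <- out[order(out$pair_id, out$twin), ]
  rownames(out) <- NULL
  structure(out, class = c("twin_cohort", "data.frame"), rater = rater)
}

#' Append indicator (item) columns to a cohort
#'
#' Generates continuous indicators for the p trait from per-wave loading
#' vectors: `item_k = loading_k * factor + noise`, with unique variance
#' `1 - loading_k^2` so items have unit variance when the factor does.
#' The factor is the cohort's observed (z-scored) p score at that wave.
#'
#' @param cohort A `twin_cohort`.
#' @param spec The generating [gen_spec()]; `spec$item_loadings` must be a
#'   list of loading vectors, one per wave (or `NULL`/empty for a no-op).
#' @return The cohort with `item_<rater>_<wave>_<k>` columns appended.
#' @export
simulate_items <- function(cohort, spec) {
  lam_all <- spec$item_loadings
  if (is.null(lam_all) || !length(lam_all)) return(cohort)
  rater <- attr(cohort, "rater") %||% "twin"
  set.seed(sub_seed(spec$seed, 5L))  # stage 5: item noise
  for (w in seq_along(WAVES)) {
    lam <- lam_all[[w]]
    if (is.null(lam) || !length(lam)) next
    if (any(lam <= 0 | lam > 1)) stopf("item loadings must lie in (0, 1]")
    f <- cohort[[paste0("p_", rater, "_", WAVES[w])]]
    fz <- (f - mean(f, na.rm = TRUE)) / stats::sd(f, na.rm = TRUE)
    for (k in seq_along(lam)) {
      noise <- stats::rnorm(length(fz), 0, sqrt(1 - lam[k]^2))
      cohort[[paste0("item_", rater, "_", WAVES[w], "_", k)]] <-
        lam[k] * fz + noise
    }
  }
  cohort
}

#' Blank cells to emulate the study's missing-data pattern
#'
#' Applies, deterministically given the spec seed, (a) per-wave
#' missing-completely-at-random blanking of each trait cell and (b)
#' pair-level wave-3 attrition in which a fraction of pairs lose all
#' wave-3 observations.
#'
#' @param cohort A `twin_cohort`.
#' @param spec The generating [gen_spec()] (fields `miss_wave`,
#'   `attrition3`, `seed`).
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, spec) {
  if (any(spec$miss_wave < 0 | spec$miss_wave > 1) ||
      spec$attrition3 < 0 || spec$attrition3 > 1)
    stopf("missingness rates must lie in [0, 1]")
  rater <- attr(cohort, "rater") %||% "twin"
  set.seed(sub_seed(spec$seed, 6L))  # stage 6: missingness
  stems <- c(paste0("p_", rater, "_"), "chaos_", "disc_")
  item_cols <- grep("^item_", names(cohort), value = TRUE)
  for (w in seq_along(WAVES)) {
    rate <- spec$miss_wave[w]
    cols <- paste0(stems, WAVES[w])
    cols <- c(cols, grep(paste0("^item_", rater, "_", WAVES[w], "_"),
                         item_cols, value = TRUE))
    if (rate > 0) {
      for (cl in cols) {
        hit <- stats::runif(nrow(cohort)) < rate
        cohort[[cl]][hit] <- NA_real_
      }
    }
  }
  if (spec$attrition3 > 0) {
    pairs <- unique(cohort$pair_id)
    lost <- pairs[stats::runif(length(pairs)) < spec$attrition3]
    cols3 <- c(paste0(stems, WAVES[3]),
               grep(paste0("_", WAVES[3], "_"), item_cols, value = TRUE))
    cohort[cohort$pair_id %in% lost, cols3] <- NA_real_
  }
  cohort
}

#' Simulate univariate twin pairs from an ACE variance profile
#'
#' Draws single-trait twin-pair observations with unit phenotypic variance
#' and the classical ACE cross-twin covariance (MZ: a2 + c2; DZ:
#' a2/2 + c2).  Used for univariate parameter-recovery experiments.
#'
#' @param n_pairs Number of pairs.
#' @param a2,c2 Additive-genetic and shared-environment variance fractions
#'   (`e2 = 1 - a2 - c2`).
#' @param prop_mz Proportion of MZ pairs.
#' @param seed Integer seed.
#' @return A data.frame with columns `pair_id`, `zygosity`, `y1`, `y2`.
#' @export
simulate_ace_pairs <- function(n_pairs, a2, c2, prop_mz = 0.344, seed = 1L) {
  e2 <- 1 - a2 - c2
  if (min(a2, c2, e2) < 0) stopf("a2, c2 and 1 - a2 - c2 must be nonnegative")
  set.seed(as.integer(seed))
  zyg <- ifelse(stats::runif(n_pairs) < prop_mz, "MZ", "DZ")
  gA0 <- stats::rnorm(n_pairs); gA1 <- stats::rnorm(n_pairs)
  gA2 <- stats::rnorm(n_pairs)
  rA <- ifelse(zyg == "MZ", 1, 0.5)
  A1 <- sqrt(rA) * gA0 + sqrt(1 - rA) * gA1
  A2 <- sqrt(rA) * gA0 + sqrt(1 - rA) * gA2
  C0 <- stats::rnorm(n_pairs)
  y1 <- sqrt(a2) * A1 + sqrt(c2) * C0 + sqrt(e2) * stats::rnorm(n_pairs)
  y2 <- sqrt(a2) * A2 + sqrt(c2) * C0 + sqrt(e2) * stats::rnorm(n_pairs)
  data.frame(pair_id = seq_len(n_pairs), zygosity = zyg, y1 = y1, y2 = y2)
}

#' Simulate singleton data from a phenotypic cross-lagged model
#'
#' Draws independent cases from a bivariate three-wave lag-1 process with
#' stated wave-1 covariance, transition matrices and innovation
#' covariances — the phenotypic analogue of the twin generator, used for
#' cross-lagged panel model recovery experiments.
#'
#' @param n Number of cases.
#' @param sigma1 2x2 wave-1 covariance.
#' @param B12,B23 2x2 transition matrices (rows = outcome trait).
#' @param psi2,psi3 2x2 innovation covariances.
#' @param seed Integer seed.
#' @return A data.frame with columns `P9, H9, P12, H12, P16, H16`.
#' @export
simulate_clpm <- function(n, sigma1, B12, B23, psi2, psi3, seed = 1L) {
  set.seed(as.integer(seed))
  draw <- function(cov2) matrix(stats::rnorm(n * 2), n, 2) %*% t(mat_sqrt(cov2))
  y1 <- draw(sigma1)
  y2 <- y1 %*% t(B12) + draw(psi2)
  y3 <- y2 %*% t(B23) + draw(psi3)
  out <- as.data.frame(cbind(y1, y2, y3))
  names(out) <- c("P9", "H9", "P12", "H12", "P16", "H16")
  out
}

#' Standardized cross-lagged process as explicit matrices
#'
#' Helper that converts standardized lag-1 dynamics (unit-variance
#' variables at every wave) into the raw matrices consumed by
#' [simulate_clpm()]: wave-1 correlation `r1`, transition matrices equal to
#' the standardized paths, and innovation covariances that top each trait
#' back up to unit variance with innovation correlation `r_innov`.
#'
#' @param B12,B23 2x2 standardized transition matrices.
#' @param r1 Wave-1 cross-trait correlation.
#' @param r_innov Innovation cross-trait correlation (waves 2 and 3).
#' @return List with elements `sigma1`, `B12`, `B23`, `psi2`, `psi3`.
#' @export
clpm_process <- function(B12, B23, r1 = 0.3, r_innov = 0.2) {
  sigma1 <- matrix(c(1, r1, r1, 1), 2, 2)
  innov <- function(B, sig) {
    d <- 1 - diag(B %*% sig %*% t(B))
    if (any(d <= 0)) stopf("standardized paths imply nonpositive innovation")
    matrix(c(d[1], r_innov * sqrt(d[1] * d[2]),
             r_innov * sqrt(d[1] * d[2]), d[2]), 2, 2)
  }
  psi2 <- innov(B12, sigma1)
  sigma2 <- symm(B12 %*% sigma1 %*% t(B12) + psi2)
  psi3 <- innov(B23, sigma2)
  list(sigma1 = sigma1, B12 = B12, B23 = B23, psi2 = psi2, psi3 = psi3)
}
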