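# MZ-differences design: within-pair difference scores among identical
# twins cancel additive-genetic and shared-environmental influences
# exactly, isolating nonshared-environment dynamics.

#' Within-pair MZ difference scores
#'
#' Excludes DZ pairs, randomly assigns twin order per pair (seeded), and
#' returns per-wave, per-trait difference scores (first minus second in
#' the randomized order).  A difference is missing if either member is
#' missing at that cell.
#'
#' @param cohort A residualized `twin_cohort` with home-composite columns.
#' @param seed Integer seed for the order randomization.
#' @param rater Which rater's p score to difference.
#' @param cols Trait columns to difference (default: the six analysis
#'   columns p/he at each wave, plus chaos/discipline when present).
#' @return A `mz_diff` data.frame, one row per MZ pair, with `d_<col>`
#'   columns and a `descriptives` attribute (mean, SD per column).
#' @export
mz_differences <- function(cohort, seed = 1L,
                           rater = attr(cohort, "rater") %||% "twin",
                           cols = NULL) {
  if (is.null(cols)) {
    cols <- c(paste0("p_", rater, "_", WAVES), paste0("he_", WAVES),
              paste0("chaos_", WAVES), paste0("disc_", WAVES))
    cols <- intersect(cols, names(cohort))
  }
  mz <- cohort[cohort$zygosity == "MZ", , drop = FALSE]
  if (!nrow(mz)) stopf("no MZ pairs in the cohort")
  t1 <- mz[mz$twin == 1, c("pair_id", cols)]
  t2 <- mz[mz$twin == 2, c("pair_id", cols)]
  m <- merge(t1, t2, by = "pair_id", suffixes = c("_t1", "_t2"))
  set.seed(as.integer(seed))
  flip <- sample(c(1, -1), nrow(m), replace = TRUE)
  out <- data.frame(pair_id = m$pair_id)
  for (cl in cols)
    out[[paste0("d_", cl)]] <-
      flip * (m[[paste0(cl, "_t1")]] - m[[paste0(cl, "_t2")]])
  desc <- data.frame(
    column = paste0("d_", cols),
    mean = sapply(cols, function(cl) mean(out[[paste0("d_", cl)]],
                                          na.rm = TRUE)),
    sd = sapply(cols, function(cl) stats::sd(out[[paste0("d_", cl)]],
                                             na.rm = TRUE)),
    n = sapply(cols, function(cl) sum(!is.na(out[[paste0("d_", cl)]]))))
  rownames(desc) <- NULL
  structure(out, class = c("mz_diff", "data.frame"), rater = rater,
            descriptives = desc)
}

#' Correlation matrix of MZ difference scores
#'
#' Pairwise-complete Pearson correlations across all difference columns;
#' constant columns give undefined (NA) entries with a warning.
#'
#' @param diff An [mz_differences()] table.
#' @return Correlation matrix over the `d_` columns.
#' @export
diff_correlations <- function(diff) {
  cols <- grep("^d_", names(diff), value = TRUE)
  if (nrow(diff) < 3) stopf("need at least 3 pairs")
  X <- as.matrix(diff[, cols, drop = FALSE])
  const <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE))
    warning("constant difference column(s): ",
            paste(cols[which(const)], collapse = ", "), call. = FALSE)
  suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
}

#' Cross-lagged panel model on MZ difference scores
#'
#' Fits the phenotypic CLPM (see [fit_clpm()]) to the within-pair p and
#' home-environment difference scores.  Because differencing cancels the
#' A and C components exactly, the difference process follows the
#' E-component transitions: the fitted standardized paths estimate the
#' standardized nonshared-environment paths.
#'
#' @param diff An [mz_differences()] table.
#' @param n_boot Bootstrap draws for path CIs (0 skips the bootstrap).
#' @param seed Bootstrap seed.
#' @param rater Which rater's differenced p score to use.
#' @return A `clpm_fit` (with `ci` attached when bootstrapped).
#' @export
fit_diff_clpm <- function(diff, n_boot = 1000L, seed = 1L,
                          rater = attr(diff, "rater") %||% "twin") {
  cols <- paste0("d_", pair_columns(rater))
  miss <- setdiff(cols, names(diff))
  if (length(miss))
    stopf("difference table lacks columns: %s", paste(miss, collapse = ", "))
  Y <- diff[, cols]
  names(Y) <- CLPM_VARS
  fit <- fit_clpm(Y)
  if (n_boot > 0) {
    bs <- bootstrap_clpm(Y, n_boot = n_boot, seed = seed)
    fit$paths$lo <- bs$ci$lo
    fit$paths$hi <- bs$ci$hi
    fit$ci <- bs$ci
  }
  fit
}
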