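# Bivariate three-wave phenotypic cross-lagged panel model (CLPM):
# each wave regressed on the immediately preceding wave only, innovation
# covariances free within wave, wave-1 covariance free.  ML via the
# recursive factorization on complete data, FIML otherwise.

CLPM_VARS <- c("P9", "H9", "P12", "H12", "P16", "H16")

clpm_implied <- function(sigma1, B12, psi2, B23, psi3) {
  s1 <- symm(sigma1)
  c21 <- B12 %*% s1
  s2 <- symm(B12 %*% s1 %*% t(B12) + psi2)
  c31 <- B23 %*% c21
  c32 <- B23 %*% s2
  s3 <- symm(B23 %*% s2 %*% t(B23) + psi3)
  out <- matrix(0, 6, 6, dimnames = list(CLPM_VARS, CLPM_VARS))
  out[1:2, 1:2] <- s1
  out[3:4, 1:2] <- c21; out[1:2, 3:4] <- t(c21)
  out[3:4, 3:4] <- s2
  out[5:6, 1:2] <- c31; out[1:2, 5:6] <- t(c31)
  out[5:6, 3:4] <- c32; out[3:4, 5:6] <- t(c32)
  out[5:6, 5:6] <- s3
  symm(out)
}

# Closed-form ML from a 6x6 ML covariance matrix (complete data): the
# likelihood of the recursive lag-1 model factorizes, so path estimates
# are the equation-wise least-squares solutions.
clpm_from_cov <- function(S) {
  sigma1 <- S[1:2, 1:2]
  B12 <- S[3:4, 1:2] %*% solve(sigma1)
  psi2 <- symm(S[3:4, 3:4] - B12 %*% S[1:2, 1:2] %*% t(B12))
  S2 <- S[3:4, 3:4]
  B23 <- S[5:6, 3:4] %*% solve(S2)
  psi3 <- symm(S[5:6, 5:6] - B23 %*% S2 %*% t(B23))
  list(sigma1 = sigma1, B12 = B12, psi2 = psi2, B23 = B23, psi3 = psi3)
}

clpm_pack <- function(th) {
  c(th$mu, vech_lower(t(chol(psd_project(th$sigma1, 1e-8) + 1e-10 * diag(2)))),
    as.numeric(th$B12),
    vech_lower(t(chol(psd_project(th$psi2, 1e-8) + 1e-10 * diag(2)))),
    as.numeric(th$B23),
    vech_lower(t(chol(psd_project(th$psi3, 1e-8) + 1e-10 * diag(2)))))
}

clpm_unpack <- function(par) {
  L1 <- unvech_lower(par[7:9], 2)
  L2 <- unvech_lower(par[14:16], 2)
  L3 <- unvech_lower(par[21:23], 2)
  list(mu = par[1:6],
       sigma1 = tcrossprod(L1),
       B12 = matrix(par[10:13], 2, 2),
       psi2 = tcrossprod(L2),
       B23 = matrix(par[17:20], 2, 2),
       psi3 = tcrossprod(L3))
}

clpm_path_table <- function(B12, B23, sigma1, psi2, psi3) {
  Sig <- clpm_implied(sigma1, B12, psi2, B23, psi3)
  sds <- sqrt(diag(Sig))
  std_B <- function(B, from, to)
    B * outer(1 / sds[to], sds[from])
  s12 <- std_B(B12, 1:2, 3:4)
  s23 <- std_B(B23, 3:4, 5:6)
  cor2 <- function(m) m[1, 2] / sqrt(m[1, 1] * m[2, 2])
  paths <- c("P9->P12", "H9->P12", "P9->H12", "H9->H12",
             "P12->P16", "H12->P16", "P12->H16", "H12->H16",
             "r_P9H9", "r_innov12", "r_innov16")
  est <- c(B12[1, 1], B12[1, 2], B12[2, 1], B12[2, 2],
           B23[1, 1], B23[1, 2], B23[2, 1], B23[2, 2],
           NA, NA, NA)
  std <- c(s12[1, 1], s12[1, 2], s12[2, 1], s12[2, 2],
           s23[1, 1], s23[1, 2], s23[2, 1], s23[2, 2],
           cor2(sigma1), cor2(psi2), cor2(psi3))
  data.frame(path = paths, estimate = est, std = std)
}

#' Fit the phenotypic cross-lagged panel model
#'
#' Fits the bivariate lag-1 model over three waves to a table of singleton
#' observations (columns `P9, H9, P12, H12, P16, H16`).  On complete data
#' the maximum-likelihood estimates are the equation-wise least-squares
#' coefficients of each wave on its predecessor (the likelihood of the
#' recursive structure factorizes); with missing cells the casewise FIML
#' likelihood is maximized numerically.  Standardized paths use the
#' model-implied SDs; cross-sectional parameters are reported as
#' correlations.
#'
#' @param data 6-column data frame/matrix in the order above.
#' @param method `"auto"` (closed form when complete, FIML otherwise),
#'   `"closed"` or `"fiml"`.
#' @return A `clpm_fit`: raw matrices, `paths` table with standardized
#'   estimates, implied covariance, [model_fit_stats()] row (`df = 4`),
#'   `n_used`.
#' @export
fit_clpm <- function(data, method = c("auto", "closed", "fiml")) {
  method <- match.arg(method)
  Y <- as.matrix(data[, CLPM_VARS[CLPM_VARS %in% colnames(data)], drop = FALSE])
  if (ncol(Y) != 6) {
    if (ncol(data) == 6) { Y <- as.matrix(data); colnames(Y) <- CLPM_VARS }
    else stopf("data must contain the six columns %s",
               paste(CLPM_VARS, collapse = ", "))
  }
  storage.mode(Y) <- "double"
  any_data <- rowSums(!is.na(Y)) > 0
  Y <- Y[any_data, , drop = FALSE]
  if (nrow(Y) < 50) stopf("need at least 50 cases with any data")
  complete <- !anyNA(Y)
  if (method == "auto") method <- if (complete) "closed" else "fiml"
  if (method == "closed") {
    if (!complete) stopf("closed-form ML requires complete data")
    n <- nrow(Y)
    mu <- colMeans(Y)
    S <- crossprod(sweep(Y, 2, mu)) / n
    qr1 <- qr(S[1:2, 1:2])
    if (qr1$rank < 2) stopf("rank-deficient predictors at wave 1")
    th <- clpm_from_cov(S)
    th$mu <- mu
    Svar <- S * n / (n - 1)
  } else {
    pats <- fiml_patterns(Y)
    n <- attr(pats, "n_used")
    pw <- pairwise_moments(Y)
    th0 <- clpm_from_cov(pw$S)
    th0$mu <- pw$mu
    obj <- function(par) {
      q <- clpm_unpack(par)
      fiml_loglik(pats, q$mu,
                  clpm_implied(q$sigma1, q$B12, q$psi2, q$B23, q$psi3))
    }
    best <- fiml_maximize(clpm_pack(th0), obj)
    if (best$convergence != 0)
      stopf("CLPM FIML did not converge (best loglik %.3f)", best$value)
    th <- clpm_unpack(best$par)
    mu <- th$mu
    Svar <- if (complete) stats::cov(Y) else pw$S
  }
  implied <- clpm_implied(th$sigma1, th$B12, th$psi2, th$B23, th$psi3)
  fit <- model_fit_stats(Svar, implied, n, df_model = 4)
  structure(
    list(B12 = th$B12, B23 = th$B23, sigma1 = symm(th$sigma1),
         psi2 = symm(th$psi2), psi3 = symm(th$psi3), means = th$mu,
         implied = implied,
         paths = clpm_path_table(th$B12, th$B23, th$sigma1, th$psi2, th$psi3),
         fit = fit, n_used = n, method = method),
    class = "clpm_fit")
}

#' Standardize the paths of a fitted CLPM
#'
#' Rescales each raw path by the ratio of model-implied predictor and
#' outcome SDs (`beta = b * sd_pred / sd_out`) and converts the
#' cross-sectional parameters to correlations.  [fit_clpm()] already
#' reports these; this recomputes the table (e.g. after editing the raw
#' matrices).
#'
#' @param fit A `clpm_fit`.
#' @return The fit with its `paths` table refreshed.
#' @export
standardize_paths <- function(fit) {
  sds <- sqrt(diag(fit$implied))
  if (any(sds == 0)) stopf("zero implied SD")
  fit$paths <- clpm_path_table(fit$B12, fit$B23, fit$sigma1,
                               fit$psi2, fit$psi3)
  fit
}

#' @export
print.clpm_fit <- function(x, ...) {
  cat(sprintf("Cross-lagged panel model (%s, n = %d)\n", x$method, x$n_used))
  print(transform(x$paths, estimate = round(estimate, 3),
                  std = round(std, 3)), row.names = FALSE)
  cat(sprintf("chi2(%d) = %.2f, CFI = %.3f, RMSEA = %.3f\n",
              x$fit$df, x$fit$chi_square, x$fit$CFI, x$fit$RMSEA))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for CLPM paths
#'
#' Case-resampling at the row level (rows are one independent singleton
#' per pair) with percentile 2.5/97.5 bounds on every standardized path;
#' deterministic given the seed.
#'
#' @param data As for [fit_clpm()].
#' @param n_boot Number of resamples (>= 200).
#' @param seed Integer seed.
#' @param method Passed to [fit_clpm()].
#' @return List with `ci` (data.frame `path`, `lo`, `hi`), `boot` (matrix
#'   of resampled standardized paths) and `n_fail`.
#' @export
bootstrap_clpm <- function(data, n_boot = 1000L, seed = 1L,
                           method = c("auto", "closed", "fiml")) {
  method <- match.arg(method)
  if (n_boot < 200) stopf("n_boot must be at least 200")
  Y <- as.matrix(data[, CLPM_VARS[CLPM_VARS %in% colnames(data)], drop = FALSE])
  if (ncol(Y) != 6) { Y <- as.matrix(data); colnames(Y) <- CLPM_VARS }
  storage.mode(Y) <- "double"
  complete <- !anyNA(Y)
  fast <- complete && method != "fiml"
  set.seed(as.integer(seed))
  n <- nrow(Y)
  res <- matrix(NA_real_, n_boot, 11L)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    std <- tryCatch({
      if (fast) {
        Yb <- Y[idx, , drop = FALSE]
        mu <- colMeans(Yb)
        S <- crossprod(sweep(Yb, 2, mu)) / n
        th <- clpm_from_cov(S)
        clpm_path_table(th$B12, th$B23, th$sigma1, th$psi2, th$psi3)$std
      } else {
        fit_clpm(Y[idx, , drop = FALSE], method = method)$paths$std
      }
    }, error = function(e) NULL)
    if (is.null(std)) fails <- fails + 1L else res[b, ] <- std
  }
  if (fails > 0.05 * n_boot)
    stopf("bootstrap resample fits failed in %d of %d draws", fails, n_boot)
  ci <- t(apply(res, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  paths <- clpm_path_table(diag(2), diag(2), diag(2), diag(2), diag(2))$path
  list(ci = data.frame(path = paths, lo = ci[, 1], hi = ci[, 2]),
       boot = res, n_fail = fails)
}
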