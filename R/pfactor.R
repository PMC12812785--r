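# Single-factor confirmatory factor analysis (data-reduction device for a
# general psychopathology score) with FIML, regression-method factor
# scores, and SEM fit statistics.

#' Maximum-likelihood fit statistics for a covariance structure
#'
#' Computes the standard ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`, the chi-square
#' `(n - 1) F`, incremental indices against the independence baseline
#' (CFI, TLI), RMSEA, SRMR on correlation residuals, and information
#' criteria.  A saturated model (`df_model = 0`) reports RMSEA 0 by
#' convention.
#'
#' @param sample_cov,implied_cov Conformable covariance matrices.
#' @param n Sample size.
#' @param df_model Model degrees of freedom (moments minus free
#'   covariance-structure parameters).
#' @return A `fit_stats` data.frame row with `chi_square`, `df`, `CFI`,
#'   `TLI`, `RMSEA`, `SRMR`, `AIC`, `BIC`, `loglik`.
#' @export
model_fit_stats <- function(sample_cov, implied_cov, n, df_model) {
  S <- as.matrix(sample_cov); Sig <- as.matrix(implied_cov)
  p <- ncol(S)
  if (!all(dim(S) == dim(Sig))) stopf("matrices are not conformable")
  ldS <- logdet(S); ldSig <- logdet(Sig)
  if (is.na(ldSig)) stopf("implied covariance is singular")
  if (is.na(ldS)) stopf("sample covariance is singular")
  inv <- solve(Sig)
  Fml <- ldSig + sum(inv * S) - ldS - p
  chisq <- max((n - 1) * Fml, 0)
  # independence baseline
  Sb <- diag(diag(S))
  Fb <- logdet(Sb) + sum(diag(S) / diag(Sb)) - ldS - p
  chisq_b <- max((n - 1) * Fb, 0)
  df_b <- p * (p - 1) / 2
  num <- max(chisq - df_model, 0)
  den <- max(chisq_b - df_b, chisq - df_model, 0)
  CFI <- if (den == 0) 1 else 1 - num / den
  TLI <- if (df_model == 0 || df_b == 0 || chisq_b / df_b <= 1) 1 else
    ((chisq_b / df_b) - (chisq / df_model)) / ((chisq_b / df_b) - 1)
  RMSEA <- if (df_model == 0) 0 else
    sqrt(max(chisq - df_model, 0) / (df_model * (n - 1)))
  Dinv <- diag(1 / sqrt(diag(S)))
  resid <- Dinv %*% (S - Sig) %*% Dinv
  SRMR <- sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2))
  k <- p * (p + 1) / 2 - df_model
  ll <- -((n - 1) / 2) * (ldSig + sum(inv * S) + p * log(2 * pi))
  data.frame(chi_square = chisq, df = df_model, CFI = CFI, TLI = TLI,
             RMSEA = RMSEA, SRMR = SRMR,
             AIC = -2 * ll + 2 * k, BIC = -2 * ll + log(n) * k, loglik = ll)
}

cfa_implied <- function(lambda, theta) {
  tcrossprod(lambda) + diag(theta, length(lambda))
}

#' Fit a one-factor model by FIML
#'
#' Maximum-likelihood single-factor solution with factor variance fixed to
#' 1 for identification (making loadings comparable across waves) and the
#' first indicator's loading constrained nonnegative by sign convention.
#' Missing data are handled by the casewise Gaussian likelihood over each
#' row's observed subvector.  Uniquenesses are kept positive during
#' optimization via a log parameterization; solutions heading for a
#' Heywood case are clamped at 1e-6 with a warning.
#'
#' @param items Data frame or matrix of at least 3 indicator columns.
#' @param restarts Jittered restarts before declaring non-convergence.
#' @return A `cfa_model`: `loadings`, `uniquenesses`, `means`, `fit`
#'   ([model_fit_stats()] row), `loglik`, `loglik_start`, `n`, `heywood`,
#'   `converged`.
#' @export
fit_cfa <- function(items, restarts = 5L) {
  Y <- as.matrix(items)
  p <- ncol(Y)
  if (p < 3) stopf("need at least 3 indicators")
  pats <- fiml_patterns(Y)
  n <- attr(pats, "n_used")
  if (n <= 2 * p + p) stopf("sample too small for the parameter count")
  pw <- pairwise_moments(Y)
  # start: first principal component of the pairwise correlation matrix
  D <- sqrt(diag(pw$S))
  R <- pw$S / outer(D, D)
  e <- eigen(R, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(max(e$values[1], 1)) * D
  if (lam0[1] < 0) lam0 <- -lam0
  th0 <- pmax(diag(pw$S) - lam0^2, 0.05 * diag(pw$S))
  unpack <- function(par) {
    list(mu = par[1:p], lambda = par[p + 1:p],
         theta = pmax(exp(par[2 * p + 1:p]), 1e-6))
  }
  obj <- function(par) {
    q <- unpack(par)
    fiml_loglik(pats, q$mu, cfa_implied(q$lambda, q$theta))
  }
  par0 <- c(pw$mu, lam0, log(th0))
  ll0 <- obj(par0)
  best <- fiml_maximize(par0, obj, restarts = restarts)
  q <- unpack(best$par)
  if (q$lambda[1] < 0) q$lambda <- -q$lambda
  heywood <- any(q$theta <= 1.01e-6)
  if (heywood)
    warning("Heywood case: uniqueness clamped at 1e-6", call. = FALSE)
  implied <- cfa_implied(q$lambda, q$theta)
  df_model <- p * (p + 1) / 2 - 2 * p
  fit <- model_fit_stats(pw$S, implied, n, df_model)
  structure(
    list(loadings = q$lambda, uniquenesses = q$theta, means = q$mu,
         implied = implied, fit = fit, loglik = best$value,
         loglik_start = ll0, n = n, heywood = heywood,
         converged = best$convergence == 0),
    class = "cfa_model")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat(sprintf("One-factor FIML model (n = %d, loglik = %.2f)\n", x$n,
              x$loglik))
  print(round(rbind(loading = x$loadings, uniqueness = x$uniquenesses), 3))
  invisible(x)
}

#' Regression-method factor scores
#'
#' Scores each case as `lambda' Sigma^-1 (y - mu)` over that case's
#' observed indicators (submatrix inversion per missingness pattern) and
#' standardizes the scores over the sample.  Cases with no observed
#' indicator are scored as missing.
#'
#' @param model A fitted [fit_cfa()] model.
#' @param items Indicator table compatible with the model.
#' @return Numeric vector of standardized factor scores.
#' @export
factor_scores <- function(model, items) {
  Y <- as.matrix(items)
  if (ncol(Y) != length(model$loadings))
    stopf("indicator count does not match the model")
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  scores <- rep(NA_real_, nrow(Y))
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- which(obs[idx[1], ])
    if (!length(o)) next
    w <- solve(model$implied[o, o, drop = FALSE],
               model$loadings[o])
    yc <- sweep(Y[idx, o, drop = FALSE], 2, model$means[o])
    scores[idx] <- yc %*% w
  }
  (scores - mean(scores, na.rm = TRUE)) / stats::sd(scores, na.rm = TRUE)
}
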