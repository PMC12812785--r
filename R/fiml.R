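# Full-information maximum-likelihood (FIML) machinery.
#
# The casewise Gaussian log-likelihood over each observation's non-missing
# subvector (valid under missing-at-random) is computed from sufficient
# statistics grouped by missingness pattern: for pattern g with observed
# index set o, n_g rows, sample mean m_g and (ML, /n) scatter S_g,
#   ll_g = -n_g/2 [ k_g log 2pi + log|S_oo| + tr(S_g S_oo^-1)
#                   + (m_g - mu_o)' S_oo^-1 (m_g - mu_o) ].

#' @noRd
fiml_patterns <- function(Y) {
  Y <- as.matrix(Y)
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- lapply(split(seq_len(nrow(Y)), key), function(idx) {
    o <- which(obs[idx[1], ])
    sub <- Y[idx, o, drop = FALSE]
    n <- nrow(sub)
    m <- colMeans(sub)
    S <- if (n > 1) crossprod(sweep(sub, 2, m)) / n else
      matrix(0, length(o), length(o))
    list(o = o, n = n, mean = m, S = S)
  })
  attr(out, "n_used") <- nrow(Y)
  out
}

#' @noRd
fiml_loglik <- function(patterns, mu, sigma) {
  ll <- 0
  for (g in patterns) {
    so <- sigma[g$o, g$o, drop = FALSE]
    ld <- logdet(so)
    if (is.na(ld)) return(-Inf)
    inv <- tryCatch(solve(so), error = function(e) NULL)
    if (is.null(inv)) return(-Inf)
    d <- g$mean - mu[g$o]
    ll <- ll - g$n / 2 * (length(g$o) * log(2 * pi) + ld +
                            sum(inv * g$S) + drop(t(d) %*% inv %*% d))
  }
  ll
}

# Pairwise-complete covariance and means, PSD-projected; used for starting
# values and for approximate fit statistics under missingness.
pairwise_moments <- function(Y) {
  Y <- as.matrix(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  S <- suppressWarnings(stats::cov(Y, use = "pairwise.complete.obs"))
  S[is.na(S)] <- 0
  n_eff <- min(colSums(!is.na(Y)))
  list(mu = mu, S = psd_project(S, floor = 1e-6), n_eff = n_eff)
}

# Generic BFGS maximization of a FIML objective with jittered restarts.
# Restart jitter is drawn from a locally seeded stream (ambient RNG state
# is saved and restored) so fits are reproducible regardless of caller
# RNG state.
fiml_maximize <- function(par, fn, restarts = 5L, reltol = 1e-8,
                          maxit = 2000L, jitter_sd = 0.05) {
  best <- NULL
  par0 <- par
  if (restarts > 1L) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(285714L)
    jitters <- matrix(stats::rnorm((restarts - 1L) * length(par0), 0,
                                   jitter_sd), nrow = restarts - 1L)
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old_seed, envir = globalenv())
  }
  for (r in seq_len(restarts)) {
    p <- if (r == 1L) par0 else par0 + jitters[r - 1L, ]
    res <- tryCatch(
      stats::optim(p, fn, method = "BFGS",
                   control = list(fnscale = -1, maxit = maxit,
                                  reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value > best$value) best <- res
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best))
    stopf("optimization failed in all %d starts", restarts)
  best
}
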