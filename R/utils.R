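# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

TRAITS <- c("P", "H")
WAVES <- c(9L, 12L, 16L)

#' @noRd
is_symmetric_psd <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol) return(FALSE)
  min(eigen(symm(m), symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

symm <- function(m) (m + t(m)) / 2

# Symmetric matrix square root; tolerates exactly singular (including zero)
# matrices, which chol() would not.
mat_sqrt <- function(m) {
  e <- eigen(symm(m), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Clip a nearly-PSD matrix onto the PSD cone (used for moment-based starting
# values, where sampling noise can push small eigenvalues negative).
psd_project <- function(m, floor = 0) {
  e <- eigen(symm(m), symmetric = TRUE)
  vals <- pmax(e$values, floor)
  symm(e$vectors %*% (vals * t(e$vectors)))
}

logdet <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  as.numeric(d$modulus)
}

# Deterministic sub-seed stream: one cohort seed fans out to the package's
# draw stages in a fixed, documented order (see simulate_cohort).
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483563)
}

# Lower-triangular vector <-> matrix (for Cholesky-style parameter packing)
vech_lower <- function(m) m[lower.tri(m, diag = TRUE)]

unvech_lower <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
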