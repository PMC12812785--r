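# A/C/E decomposition of stability and cross-lagged paths, and the inverse
# problem of building a generating model with prescribed path shares.

get_processes <- function(x) {
  if (inherits(x, "genspec") || inherits(x, "biometric_fit"))
    return(x$processes)
  if (is.list(x) && all(c("A", "C", "E") %in% names(x))) return(x)
  stopf("cannot extract component processes from this object")
}

# Per-component covariance at the predictor wave of each transition.
component_wave_sigmas <- function(procs) {
  lapply(procs, function(p) {
    s1 <- symm(p$sigma1)
    s2 <- symm(p$B12 %*% s1 %*% t(p$B12) + p$psi2)
    list(s1, s2)
  })
}

share_vector <- function(contrib) {
  tot <- sum(contrib)
  if (all(contrib >= -1e-12) || all(contrib <= 1e-12)) {
    if (abs(tot) < 1e-12) return(rep(NA_real_, 3))
    100 * contrib / tot
  } else {
    100 * abs(contrib) / sum(abs(contrib))
  }
}

#' A/C/E decomposition of every stability and cross-lagged path
#'
#' For transition t, the phenotypic path matrix is
#' `B_ph = (sum_X B_X Sigma_X,t) Sigma_t^-1` with
#' `Sigma_t = sum_X Sigma_X,t`; the contribution of component X to entry
#' (k, j) is `[B_X Sigma_X,t Sigma_t^-1]_kj`.  Contributions are signed
#' and sum exactly to the phenotypic path; percentage shares divide by the
#' phenotypic path when all contributions share its sign, and by the sum
#' of absolute contributions when signs are mixed (guaranteeing
#' nonnegative percentages that sum to 100).
#'
#' @param x A `genspec` (ground truth) or `biometric_fit` (estimates).
#' @return A data.frame with one row per path (`P->P`, `H->H`, `P->H`,
#'   `H->P` at transitions 9-12 and 12-16): signed raw contributions
#'   `raw_A/C/E`, the phenotypic path, and percentage shares `pA/pC/pE`.
#' @export
decompose_paths <- function(x) {
  procs <- get_processes(x)
  sigs <- component_wave_sigmas(procs)
  rows <- list()
  for (t in 1:2) {
    sig_t <- lapply(sigs, `[[`, t)
    tot <- Reduce(`+`, sig_t)
    inv <- tryCatch(solve(tot), error = function(e)
      stopf("singular phenotypic covariance at transition %d", t))
    K <- lapply(c(A = "A", C = "C", E = "E"), function(xn) {
      B <- if (t == 1) procs[[xn]]$B12 else procs[[xn]]$B23
      B %*% sig_t[[xn]] %*% inv
    })
    Bph <- Reduce(`+`, K)
    for (k in 1:2) for (j in 1:2) {
      contrib <- sapply(K, function(m) m[k, j])
      sh <- share_vector(contrib)
      rows[[length(rows) + 1L]] <- data.frame(
        path = sprintf("%s%d->%s%d", TRAITS[j], WAVES[t],
                       TRAITS[k], WAVES[t + 1]),
        transition = t, from = TRAITS[j], to = TRAITS[k],
        raw_A = contrib[1], raw_C = contrib[2], raw_E = contrib[3],
        phenotypic = Bph[k, j],
        pA = sh[1], pC = sh[2], pE = sh[3])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' A/C/E shares of wave-specific (innovation) variance
#'
#' For waves 2 and 3 and each trait, the share of the innovation variance
#' (the variance unique to that wave after accounting for transmission
#' from earlier waves) carried by each component; wave 1 reports the
#' initial variance decomposition.  Waves with (numerically) zero total
#' innovation variance are reported as missing and flagged.
#'
#' @param x A `genspec` or `biometric_fit`.
#' @return Data.frame with columns `wave`, `trait`, `pA`, `pC`, `pE`,
#'   `total`, `defined`.
#' @export
unique_variance <- function(x) {
  procs <- get_processes(x)
  pick <- function(p, w) switch(w, p$sigma1, p$psi2, p$psi3)
  rows <- list()
  for (w in 1:3) for (k in 1:2) {
    v <- sapply(procs, function(p) pick(p, w)[k, k])
    tot <- sum(v)
    defined <- tot > 1e-12
    sh <- if (defined) 100 * v / tot else rep(NA_real_, 3)
    rows[[length(rows) + 1L]] <- data.frame(
      wave = WAVES[w], trait = TRAITS[k],
      pA = sh[1], pC = sh[2], pE = sh[3], total = tot, defined = defined)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fill in a partially specified share target: the named shares are fixed
# and the remainder is split across the unnamed components in proportion
# to their current (absolute) contributions on that path.
complete_shares <- function(spec, from, to, transition, partial) {
  dec <- decompose_paths(spec)
  row <- dec[dec$from == from & dec$to == to & dec$transition == transition, ]
  cur <- abs(c(A = row$raw_A, C = row$raw_C, E = row$raw_E))
  out <- c(A = NA_real_, C = NA_real_, E = NA_real_)
  out[names(partial)] <- partial
  rest <- setdiff(names(out), names(partial))
  remainder <- 1 - sum(partial)
  if (remainder < -1e-8) stopf("named shares exceed 1")
  w <- cur[rest]
  if (sum(w) <= 0) w <- rep(1, length(rest))
  out[rest] <- remainder * w / sum(w)
  out
}

#' Retarget the A/C/E shares of chosen paths in a generating model
#'
#' Rescales the component-level transition coefficients of a base
#' [gen_spec()] so the model-implied decomposition of the named paths
#' (see [decompose_paths()]) matches the requested shares exactly, while
#' the phenotypic path magnitude is held at the base model's value.  When
#' both predictor traits of an outcome row are targeted the row is solved
#' jointly; transition-1 targets are solved before transition-2 targets so
#' the wave-2 component covariances they imply are respected.
#'
#' The covariance and innovation matrices are untouched, so the modified
#' spec remains valid (PSD) by construction.
#'
#' @param spec The base `genspec`; each component must carry variance on
#'   the predictor trait of every targeted path.
#' @param from,to Predictor and outcome trait (`"P"` or `"H"`) of a single
#'   targeted path.
#' @param transition 1 (waves 9-12) or 2 (waves 12-16).
#' @param shares Length-3 shares `(A, C, E)`, nonnegative, summing to 1;
#'   or a named subset (e.g. `c(A = 0.68)`) whose remainder is split
#'   across the other components in proportion to their current
#'   contributions.
#' @param targets For `solve_shares_multi()`: a list of
#'   `list(from =, to =, transition =, shares =)` entries.
#' @return A modified `genspec` whose [decompose_paths()] reproduces the
#'   targets (to ~1e-8).
#' @export
solve_shares <- function(spec, from, to, transition, shares) {
  solve_shares_multi(spec, list(list(from = from, to = to,
                                     transition = transition,
                                     shares = shares)))
}

#' @rdname solve_shares
#' @export
solve_shares_multi <- function(spec, targets) {
  procs <- get_processes(spec)
  norm_target <- function(tg) {
    sh <- tg$shares
    if (!is.null(names(sh)) && length(sh) < 3)
      sh <- complete_shares(spec, tg$from, tg$to, tg$transition, sh)
    if (length(sh) != 3) stopf("shares must have 3 components")
    sh <- unname(sh)
    if (any(sh < -1e-12)) stopf("shares must be nonnegative")
    if (abs(sum(sh) - 1) > 1e-8) stopf("shares must sum to 1")
    tg$shares <- sh
    tg
  }
  targets <- lapply(targets, norm_target)
  for (t in 1:2) {
    tg_t <- Filter(function(tg) tg$transition == t, targets)
    if (!length(tg_t)) next
    sigs <- component_wave_sigmas(procs)
    sig_t <- lapply(sigs, `[[`, t)
    tot <- Reduce(`+`, sig_t)
    inv <- solve(tot)
    M <- lapply(sig_t, function(s) s %*% inv)  # per-component weight matrix
    Bfield <- if (t == 1) "B12" else "B23"
    Bph <- Reduce(`+`, lapply(c("A", "C", "E"), function(xn)
      procs[[xn]][[Bfield]] %*% M[[xn]]))
    for (k in 1:2) {
      row_tg <- Filter(function(tg) match(tg$to, TRAITS) == k, tg_t)
      if (!length(row_tg)) next
      js <- vapply(row_tg, function(tg) match(tg$from, TRAITS), 1L)
      if (anyDuplicated(js)) stopf("duplicate target for the same path")
      for (ci in seq_along(c("A", "C", "E"))) {
        xn <- c("A", "C", "E")[ci]
        b <- procs[[xn]][[Bfield]][k, ]
        Mx <- M[[xn]]
        if (length(js) == 2L) {
          # jointly solve both entries of the row: b' Mx = target row
          tvec <- vapply(row_tg, function(tg)
            tg$shares[ci] * Bph[k, match(tg$from, TRAITS)], 0)
          tvec <- tvec[order(js)]
          sol <- tryCatch(solve(t(Mx), tvec), error = function(e)
            stopf("infeasible target: component %s carries no signal", xn))
          b <- as.numeric(sol)
        } else {
          j <- js[1]
          tval <- row_tg[[1]]$shares[ci] * Bph[k, j]
          denom <- Mx[j, j]
          if (abs(denom) < 1e-10) {
            other <- sum(b[-j] * Mx[-j, j])
            if (abs(tval - other) > 1e-10)
              stopf("infeasible target: component %s has no variance on %s",
                    xn, TRAITS[j])
          } else {
            b[j] <- (tval - sum(b[-j] * Mx[-j, j])) / denom
          }
        }
        procs[[xn]][[Bfield]][k, ] <- b
      }
    }
  }
  spec$processes <- lapply(procs, function(p)
    component_process(p$component, p$sigma1, p$B12, p$B23, p$psi2, p$psi3))
  spec
}
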