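# Model-implied covariance structure of the twin-pair observation vector.

# Within-twin 6x6 covariance of one component process over three waves,
# observation order (P9, H9, P12, H12, P16, H16).
component_within_cov <- function(p) {
  s1 <- p$sigma1
  c21 <- p$B12 %*% s1
  s2 <- symm(p$B12 %*% s1 %*% t(p$B12) + p$psi2)
  c31 <- p$B23 %*% c21
  c32 <- p$B23 %*% s2
  s3 <- symm(p$B23 %*% s2 %*% t(p$B23) + p$psi3)
  out <- matrix(0, 6, 6)
  out[1:2, 1:2] <- s1
  out[3:4, 1:2] <- c21; out[1:2, 3:4] <- t(c21)
  out[3:4, 3:4] <- s2
  out[5:6, 1:2] <- c31; out[1:2, 5:6] <- t(c31)
  out[5:6, 3:4] <- c32; out[3:4, 5:6] <- t(c32)
  out[5:6, 5:6] <- s3
  symm(out)
}

twin_corr_factor <- function(component, zygosity) {
  switch(component,
         A = if (zygosity == "MZ") 1 else 0.5,
         C = 1,
         E = 0)
}

#' Model-implied 12x12 twin-pair covariance
#'
#' Propagates the joint two-twin latent A/C/E processes of a generating
#' model through the three waves and returns the implied covariance of the
#' stacked observation vector (twin 1: P9, H9, P12, H12, P16, H16; twin 2:
#' same order).  Within each component the cross-twin covariance at wave 1
#' is r_X sigma1 and each innovation's cross-twin covariance is r_X psi,
#' with r_A = 1 (MZ) or 0.5 (DZ), r_C = 1 and r_E = 0; because every
#' cross-twin block is proportional to its within-twin counterpart, the
#' component's cross-twin 6x6 block equals r_X times its within-twin block.
#' The phenotypic covariance sums the three components.
#'
#' @param spec A [gen_spec()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric PSD 12x12 matrix with dimnames
#'   `<trait><wave>_t<twin>`.
#' @export
build_expected_cov <- function(spec, zygosity) {
  if (!inherits(spec, "genspec")) stopf("spec must be a genspec")
  if (!zygosity %in% c("MZ", "DZ")) stopf("unknown zygosity code: %s", zygosity)
  within <- matrix(0, 6, 6)
  cross <- matrix(0, 6, 6)
  for (x in c("A", "C", "E")) {
    w <- component_within_cov(spec$processes[[x]])
    within <- within + w
    cross <- cross + twin_corr_factor(x, zygosity) * w
  }
  out <- rbind(cbind(within, cross), cbind(t(cross), within))
  nm <- paste0(rep(c("P9", "H9", "P12", "H12", "P16", "H16"), 2),
               "_t", rep(1:2, each = 6))
  dimnames(out) <- list(nm, nm)
  symm(out)
}
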