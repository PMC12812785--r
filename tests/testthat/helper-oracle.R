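# Independent brute-force oracle for the model-implied twin-pair
# covariance: enumerates the linear map M from all joint innovations
# (wave-1 states and wave-2/3 innovations of both twins) to all twelve
# observations and forms M Cov(innov) M', instead of the recursive
# construction used by the package.

oracle_expected_cov <- function(spec, zygosity) {
  out <- matrix(0, 12, 12)
  for (x in c("A", "C", "E")) {
    p <- spec$processes[[x]]
    r <- switch(x, A = if (zygosity == "MZ") 1 else 0.5, C = 1, E = 0)
    R <- matrix(c(1, r, r, 1), 2, 2)
    T1 <- kronecker(diag(2), p$B12)  # joint 2-twin transition, wave 1 -> 2
    T2 <- kronecker(diag(2), p$B23)
    D <- matrix(0, 12, 12)
    D[1:4, 1:4] <- kronecker(R, p$sigma1)
    D[5:8, 5:8] <- kronecker(R, p$psi2)
    D[9:12, 9:12] <- kronecker(R, p$psi3)
    M <- rbind(cbind(diag(4), matrix(0, 4, 8)),
               cbind(T1, diag(4), matrix(0, 4, 4)),
               cbind(T2 %*% T1, T2, diag(4)))
    out <- out + M %*% D %*% t(M)
  }
  # reorder from wave-major (t1P, t1H, t2P, t2H per wave) to twin-major
  perm <- integer(12)
  for (j in 1:2) for (t in 1:3) for (k in 1:2)
    perm[(j - 1) * 6 + (t - 1) * 2 + k] <- (t - 1) * 4 + (j - 1) * 2 + k
  unname(out[perm, perm])
}
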