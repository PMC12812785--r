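# Spec builders used across the tests.

random_psd2 <- function() {
  a <- matrix(stats::rnorm(4, sd = 0.5), 2, 2)
  crossprod(a) + 0.1 * diag(2)
}

random_process <- function(x) {
  component_process(x, sigma1 = random_psd2(),
                    B12 = matrix(stats::rnorm(4, sd = 0.3), 2, 2),
                    B23 = matrix(stats::rnorm(4, sd = 0.3), 2, 2),
                    psi2 = random_psd2(), psi3 = random_psd2())
}

random_genspec <- function(seed, ...) {
  set.seed(seed)
  gen_spec(list(A = random_process("A"), C = random_process("C"),
                E = random_process("E")),
           n_pairs = 100L, seed = seed, ...)
}

# Spec with a single active component (the others have zero variance).
single_component_spec <- function(active, B12 = diag(c(0.6, 0.4)),
                                  B23 = diag(c(0.6, 0.4)), n_pairs = 100L,
                                  seed = 1L, ...) {
  zero <- function(x) component_process(
    x, matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
    matrix(0, 2, 2), matrix(0, 2, 2))
  live <- component_process(active, diag(2), B12, B23,
                            diag(2) - B12 %*% t(B12) * 0.5,
                            diag(2) - B23 %*% t(B23) * 0.5)
  procs <- list(A = zero("A"), C = zero("C"), E = zero("E"))
  procs[[active]] <- live
  gen_spec(procs, n_pairs = n_pairs, seed = seed,
           age_effect = c(0, 0), sex_effect = c(0, 0), ...)
}

# Independent-component spec with diagonal everything (convenient for
# exact solve_shares expectations).
diagonal_spec <- function(vA = 0.5, vC = 0.2, vE = 0.3, b = 0.5,
                          n_pairs = 100L, seed = 1L, ...) {
  mk2 <- function(x, v) component_process(
    x, v * diag(2), b * diag(2), b * diag(2),
    v * (1 - b^2) * diag(2), v * (1 - b^2) * diag(2))
  gen_spec(list(A = mk2("A", vA), C = mk2("C", vC), E = mk2("E", vE)),
           n_pairs = n_pairs, seed = seed, ...)
}

# Simulate, residualize and composite-score a cohort in one step.
make_analysis_cohort <- function(spec, rater = "twin") {
  co <- simulate_cohort(spec, rater = rater)
  co <- inject_missingness(co, spec)
  co <- residualize_age_sex(co)
  add_home_composite(co)
}
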