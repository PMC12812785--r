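# Plain-text IO: the cohort CSV schema and the generating-model config.

#' Read / write the cohort CSV
#'
#' One row per twin; columns `pair_id, zygosity, twin, sex,
#' age_9, age_12, age_16`, per-wave trait columns
#' (`p_parent_*`, `p_twin_*`, `chaos_*`, `disc_*`, optionally `he_*` and
#' `item_<rater>_<wave>_<k>`); empty cells are missing; header required;
#' UTF-8.
#'
#' @param path File path.
#' @param cohort A `twin_cohort`.
#' @return `read_cohort()` returns a `twin_cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("pair_id", "zygosity", "twin", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("cohort file lacks required columns: %s",
          paste(miss, collapse = ", "))
  if (!all(df$zygosity %in% c("MZ", "DZ")))
    stopf("zygosity must be MZ or DZ")
  tab <- table(df$pair_id)
  if (any(tab != 2)) stopf("every pair must have exactly 2 rows")
  rater <- if (any(grepl("^p_twin_", names(df)))) "twin" else "parent"
  structure(df, class = c("twin_cohort", "data.frame"), rater = rater)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a generating model as a YAML config
#'
#' Serializes a [gen_spec()] with matrices stored row-major.
#'
#' @param spec A `genspec`.
#' @param path File path.
#' @return `read_genspec()` returns a `genspec`.
#' @export
write_genspec <- function(spec, path) {
  ser <- list(
    n_pairs = spec$n_pairs, prop_mz = spec$prop_mz,
    prop_female = spec$prop_female,
    age_means = spec$age_means, age_sds = spec$age_sds,
    age_effect = spec$age_effect, sex_effect = spec$sex_effect,
    chaos_disc_r = spec$chaos_disc_r,
    item_loadings = spec$item_loadings,
    miss_wave = spec$miss_wave, attrition3 = spec$attrition3,
    seed = spec$seed,
    processes = lapply(spec$processes, function(p)
      list(component = p$component,
           sigma1 = as.numeric(t(p$sigma1)), B12 = as.numeric(t(p$B12)),
           B23 = as.numeric(t(p$B23)), psi2 = as.numeric(t(p$psi2)),
           psi3 = as.numeric(t(p$psi3)))))
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_genspec
#' @export
read_genspec <- function(path) {
  ser <- yaml::read_yaml(path)
  m2 <- function(v) matrix(as.numeric(v), 2, 2, byrow = TRUE)
  procs <- lapply(ser$processes, function(p)
    component_process(p$component, m2(p$sigma1), m2(p$B12), m2(p$B23),
                      m2(p$psi2), m2(p$psi3)))
  gen_spec(procs, n_pairs = ser$n_pairs, prop_mz = ser$prop_mz,
           prop_female = ser$prop_female, age_means = as.numeric(ser$age_means),
           age_sds = as.numeric(ser$age_sds),
           age_effect = as.numeric(ser$age_effect),
           sex_effect = as.numeric(ser$sex_effect),
           chaos_disc_r = ser$chaos_disc_r,
           item_loadings = ser$item_loadings,
           miss_wave = as.numeric(ser$miss_wave),
           attrition3 = ser$attrition3, seed = ser$seed)
}
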