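# Data preparation: sex-difference summaries, age/sex residualization,
# one-twin-per-pair selection and the home-environment composite.

wave_of <- function(col) sub(".*_(9|12|16)$", "\\1", col)

cohort_trait_cols <- function(cohort) {
  grep("^(p_(twin|parent)|chaos|disc|he)_(9|12|16)$", names(cohort),
       value = TRUE)
}

#' Age- and sex-correct traits and standardize the residuals
#'
#' For every trait column at every wave, fits an ordinary least-squares
#' regression on the wave's age and a 0/1 female indicator over the
#' non-missing rows, and replaces the trait by the z-scored residual
#' (mean 0, SD 1 over non-missing cases); missing cells stay missing.
#' Both twins of a pair are pooled for coefficient estimation.
#'
#' @param cohort A `twin_cohort` with `age_<wave>` and `sex` columns.
#' @param cols Trait columns to residualize (default: every p/chaos/
#'   discipline/home column present).
#' @return The cohort with residualized traits and attribute
#'   `residualized = TRUE`.
#' @export
residualize_age_sex <- function(cohort, cols = cohort_trait_cols(cohort)) {
  if (!"sex" %in% names(cohort)) stopf("cohort has no sex column")
  sex01 <- as.numeric(cohort$sex == "F")
  for (cl in cols) {
    age <- cohort[[paste0("age_", wave_of(cl))]]
    y <- cohort[[cl]]
    ok <- !is.na(y) & !is.na(age)
    if (sum(ok) < 3) stopf("trait %s has fewer than 3 non-missing values", cl)
    fit <- stats::lm.fit(cbind(1, age[ok], sex01[ok]), y[ok])
    r <- fit$residuals
    s <- stats::sd(r)
    if (s == 0) stopf("trait %s is constant after adjustment", cl)
    out <- rep(NA_real_, length(y))
    out[ok] <- (r - mean(r)) / s
    cohort[[cl]] <- out
  }
  attr(cohort, "residualized") <- TRUE
  cohort
}

#' Share of variance explained by sex (ANOVA eta-squared)
#'
#' Between-group sum of squares over total sum of squares from a one-way
#' analysis of variance of the values on the two sex groups.
#'
#' @param values Numeric vector (missing values dropped).
#' @param sex Group labels, two distinct values among the non-missing rows.
#' @return Fraction in \[0, 1\].
#' @export
sex_eta_squared <- function(values, sex) {
  ok <- !is.na(values) & !is.na(sex)
  values <- values[ok]; sex <- factor(sex[ok])
  if (nlevels(droplevels(sex)) < 2) stopf("need two sex groups")
  # only the sums of squares are used, so the F-test's perfect-fit
  # warning is irrelevant here
  a <- suppressWarnings(stats::anova(stats::lm(values ~ sex)))
  ss <- a[["Sum Sq"]]
  ss[1] / sum(ss)
}

#' Select one random twin per pair
#'
#' Keeps a single, randomly chosen member of each pair so the rows of the
#' returned table are independent (using both twins would artificially
#' inflate the sample).  Deterministic given the seed.
#'
#' @param cohort A `twin_cohort`.
#' @param seed Integer seed.
#' @return A data.frame with exactly one row per pair.
#' @export
select_one_per_pair <- function(cohort, seed = 1L) {
  pairs <- unique(cohort$pair_id)
  set.seed(as.integer(seed))
  pick <- sample(1:2, length(pairs), replace = TRUE)
  keep <- cohort$twin == pick[match(cohort$pair_id, pairs)]
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Home-environment composite from chaos and discipline
#'
#' Elementwise mean of the two standardized inputs, re-standardized.  The
#' equal weighting follows a principal-component check in which both
#' indicators load equally on the first component.  If exactly one input
#' is missing the observed one is carried (preserving sample size); both
#' missing gives missing.
#'
#' @param chaos,discipline Numeric vectors of standardized residuals.
#' @return Standardized composite vector.
#' @export
home_composite <- function(chaos, discipline) {
  if (length(chaos) != length(discipline)) stopf("input length mismatch")
  comp <- rowMeans(cbind(chaos, discipline), na.rm = TRUE)
  comp[is.na(chaos) & is.na(discipline)] <- NA_real_
  (comp - mean(comp, na.rm = TRUE)) / stats::sd(comp, na.rm = TRUE)
}

#' Add per-wave home-composite columns to a cohort
#'
#' Applies [home_composite()] to the chaos and discipline columns of each
#' wave, writing `he_<wave>` columns.
#'
#' @param cohort A residualized `twin_cohort`.
#' @return The cohort with `he_9`, `he_12`, `he_16` appended.
#' @export
add_home_composite <- function(cohort) {
  for (w in WAVES) {
    cohort[[paste0("he_", w)]] <-
      home_composite(cohort[[paste0("chaos_", w)]],
                     cohort[[paste0("disc_", w)]])
  }
  cohort
}

#' Descriptive statistics table with sex differences
#'
#' Mean and SD of each trait column overall and by sex, plus the ANOVA
#' eta-squared for sex.
#'
#' @param cohort A `twin_cohort`.
#' @param cols Trait columns (default: all present).
#' @return A data.frame with one row per trait column.
#' @export
descriptives_table <- function(cohort, cols = cohort_trait_cols(cohort)) {
  f <- cohort$sex == "F"
  do.call(rbind, lapply(cols, function(cl) {
    y <- cohort[[cl]]
    data.frame(
      variable = cl,
      n = sum(!is.na(y)),
      mean = mean(y, na.rm = TRUE), sd = stats::sd(y, na.rm = TRUE),
      mean_f = mean(y[f], na.rm = TRUE), sd_f = stats::sd(y[f], na.rm = TRUE),
      mean_m = mean(y[!f], na.rm = TRUE), sd_m = stats::sd(y[!f], na.rm = TRUE),
      eta2_sex = sex_eta_squared(y, cohort$sex))
  }))
}
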