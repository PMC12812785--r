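# End-to-end orchestration: simulate (or load) -> preprocess -> score ->
# CLPM -> twin ACE -> MZ differences, with a plain-text report bundle.

#' Run the full analysis pipeline
#'
#' Executes the package's stages from a single configuration and writes a
#' report bundle of plain CSV/JSON files: descriptives (with sex
#' eta-squared), factor loadings and fit when items are present,
#' composite correlations, cross-lagged panel paths with bootstrap CIs,
#' univariate ACE estimates per trait and wave, the biometric cross-lagged
#' ACE decomposition, and MZ-differences outputs.  A structured log
#' records seeds and the resolved generating model so any result can be
#' regenerated.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   `input` (cohort CSV path) or `genspec` (a [gen_spec()] or YAML path);
#'   `rater` (`"twin"` or `"parent"`); logical flags `clpm`, `twin`,
#'   `mzdiff`, `separate_home` (also analyse chaos and discipline
#'   individually); `n_boot`; `seed`; `outdir`.
#' @return Invisibly, a list of the fitted objects; files are written to
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  rater <- config$rater %||% "twin"
  n_boot <- config$n_boot %||% 1000L
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  has_input <- !is.null(config$input); has_spec <- !is.null(config$genspec)
  if (has_input == has_spec)
    stopf("config must name exactly one of input / genspec")
  log <- list(seed = seed, rater = rater, n_boot = n_boot,
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("twinclpm")))

  if (has_spec) {
    spec <- config$genspec
    if (is.character(spec)) spec <- read_genspec(spec)
    cohort <- simulate_cohort(spec, rater = rater)
    cohort <- simulate_items(cohort, spec)
    cohort <- inject_missingness(cohort, spec)
    write_genspec(spec, file.path(outdir, "resolved_genspec.yaml"))
    log$genspec <- "resolved_genspec.yaml"
  } else {
    cohort <- read_cohort(config$input)
    log$input <- config$input
  }
  out <- list(cohort = cohort)

  # optional item-level scoring: one factor per wave for the chosen rater
  item_stub <- paste0("^item_", rater, "_")
  if (any(grepl(item_stub, names(cohort)))) {
    loadings <- list(); fits <- list()
    for (w in WAVES) {
      cols <- grep(paste0(item_stub, w, "_"), names(cohort), value = TRUE)
      if (length(cols) < 3) next
      model <- fit_cfa(cohort[, cols])
      cohort[[paste0("p_", rater, "_", w)]] <-
        factor_scores(model, cohort[, cols])
      loadings[[as.character(w)]] <-
        data.frame(wave = w, item = cols, loading = model$loadings,
                   uniqueness = model$uniquenesses)
      fits[[as.character(w)]] <- cbind(wave = w, model$fit)
    }
    if (length(loadings)) {
      utils::write.csv(do.call(rbind, loadings),
                       file.path(outdir, "cfa_loadings.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, fits),
                       file.path(outdir, "cfa_fit.csv"), row.names = FALSE)
    }
  }

  utils::write.csv(descriptives_table(cohort),
                   file.path(outdir, "descriptives.csv"), row.names = FALSE)
  cohort <- residualize_age_sex(cohort)
  cohort <- add_home_composite(cohort)
  out$cohort <- cohort

  analysis_sets <- list(he = "he")
  if (isTRUE(config$separate_home))
    analysis_sets <- list(he = "he", chaos = "chaos", disc = "disc")

  singles <- select_one_per_pair(cohort, seed = seed)
  comp_cols <- c(paste0("p_", rater, "_", WAVES), paste0("he_", WAVES))
  utils::write.csv(
    suppressWarnings(stats::cor(as.matrix(singles[, comp_cols]),
                                use = "pairwise.complete.obs")),
    file.path(outdir, "composite_correlations.csv"))

  for (set_name in names(analysis_sets)) {
    hom <- analysis_sets[[set_name]]
    suffix <- if (set_name == "he") "" else paste0("_", set_name)
    cols <- pair_columns(rater)
    if (hom != "he") cols <- sub("^he_", paste0(hom, "_"), cols)

    if (isTRUE(config$clpm %||% TRUE)) {
      Y <- singles[, cols]; names(Y) <- CLPM_VARS
      fit <- fit_clpm(Y)
      # each FIML refit is costly, so cap the bootstrap under missingness
      nb <- if (anyNA(Y)) min(max(200L, n_boot), 200L) else max(200L, n_boot)
      bs <- tryCatch(bootstrap_clpm(Y, n_boot = nb, seed = seed),
                     error = function(e) NULL)
      if (!is.null(bs)) { fit$paths$lo <- bs$ci$lo; fit$paths$hi <- bs$ci$hi }
      utils::write.csv(fit$paths,
                       file.path(outdir, paste0("clpm_paths", suffix, ".csv")),
                       row.names = FALSE)
      utils::write.csv(fit$fit,
                       file.path(outdir, paste0("clpm_fit", suffix, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(paths = fit$paths, fit = fit$fit, n = fit$n_used, seed = seed),
        file.path(outdir, paste0("clpm", suffix, ".json")),
        auto_unbox = TRUE, digits = NA)
      out[[paste0("clpm", suffix)]] <- fit
    }

    if (isTRUE(config$twin %||% TRUE)) {
      uni <- list()
      for (tr in c(paste0("p_", rater), hom)) for (w in WAVES) {
        fitu <- tryCatch(
          fit_univariate_ace(cohort, tr, w, n_boot = min(n_boot, 500L),
                             seed = seed),
          error = function(e) NULL)
        if (is.null(fitu)) next
        uni[[paste0(tr, "_", w)]] <- data.frame(
          trait = tr, wave = w, a2 = fitu$a2, c2 = fitu$c2, e2 = fitu$e2,
          rMZ = fitu$rMZ, rDZ = fitu$rDZ)
      }
      utils::write.csv(do.call(rbind, uni),
                       file.path(outdir,
                                 paste0("univariate_ace", suffix, ".csv")),
                       row.names = FALSE)
      if (hom == "he") {
        bio <- fit_crosslag_ace(cohort, rater = rater)
        utils::write.csv(bio$decomposition,
                         file.path(outdir, "ace_decomposition.csv"),
                         row.names = FALSE)
        utils::write.csv(bio$innovation_shares,
                         file.path(outdir, "ace_innovation_shares.csv"),
                         row.names = FALSE)
        out$crosslag_ace <- bio
      }
    }

    if (isTRUE(config$mzdiff %||% TRUE) && hom == "he") {
      diffs <- mz_differences(cohort, seed = seed, rater = rater)
      utils::write.csv(attr(diffs, "descriptives"),
                       file.path(outdir, "mzdiff_descriptives.csv"),
                       row.names = FALSE)
      utils::write.csv(diff_correlations(diffs),
                       file.path(outdir, "mzdiff_correlations.csv"))
      nb <- if (anyNA(diffs)) 0L else max(200L, n_boot)
      dfit <- fit_diff_clpm(diffs, n_boot = nb, seed = seed)
      utils::write.csv(dfit$paths,
                       file.path(outdir, "mzdiff_clpm_paths.csv"),
                       row.names = FALSE)
      out$mzdiff <- dfit
    }
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
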