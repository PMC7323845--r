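# End-to-end drivers: simulate, full bias pipeline, cross-validation.
# Each run persists tidy delimited tables plus a JSON manifest recording
# the tool version, config snapshot, master seed, and input digests, so
# every stochastic output is reproducible from (input, config, seed).

.read_config <- function(path) {
  if (is.null(path)) return(list())
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.write_manifest <- function(out_dir, stage, master_seed, config = list(),
                            inputs = character(0), extra = list(),
                            failed = FALSE) {
  manifest <- c(list(
    tool = "consentbias",
    version = as.character(utils::packageVersion("consentbias")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage = stage, master_seed = master_seed, config = config,
    input_digests = if (length(inputs)) as.list(tools::md5sum(inputs))
                    else list(),
    status = if (failed) "FAILED" else "ok"
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate and persist a synthetic population
#'
#' Writes the latent population (with `latent_` and `true_mean_` columns),
#' its observed view (a valid pipeline input), and the ground-truth bias
#' summary, plus a manifest.
#'
#' @param config A `synthetic_config`, or a path to a YAML/JSON file of
#'   [synthetic_config()] arguments, or NULL for the defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return File paths, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir, seed) {
  if (is.character(config)) config <- do.call(synthetic_config,
                                              .read_config(config))
  if (is.null(config)) config <- synthetic_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- generate_population(config, seed = seed)
  obs <- observed_view(pop)
  paths <- c(
    population = file.path(out_dir, "population_latent.csv"),
    observed = file.path(out_dir, "observed.csv"),
    truth = file.path(out_dir, "truth_summary.csv")
  )
  write_study_table(as.data.frame(pop), paths["population"], seed = seed)
  write_study_table(as.data.frame(obs), paths["observed"], seed = seed)
  write_study_table(true_bias(pop), paths["truth"], seed = seed)
  .write_manifest(out_dir, "simulate", seed,
                  config = config[setdiff(names(config), "outcome_models")])
  invisible(paths)
}

#' Run the full consent-bias pipeline
#'
#' Reads a study table, runs scoring, the consent model, multiple
#' imputation, bootstrap and PSM ensembles, and the bias report, and
#' persists every intermediate table: propensity-model summary, imputed
#' runs (long format), subsample memberships, group summary, comparison
#' table, population/bias estimates, composite-score reference parameters,
#' and a text summary.
#'
#' @param input Path to a study table (see [read_study_table()]).
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param m Runs per ensemble (default 100).
#' @param alpha Significance level (default 0.05).
#' @param config Optional YAML/JSON file with overrides
#'   (`predictors`, `proper`, `caliper`, `pool_untested`, `window`).
#' @return The `bias_report`, invisibly.
#' @export
run_pipeline <- function(input, out_dir, seed, m = 100, alpha = 0.05,
                         config = NULL) {
  cfg <- .read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_study_table(input, window = cfg$window %||% 300,
                              age_range = cfg$age_range %||% c(2, 8))
  report <- estimate_consent_bias(
    records, m = m, master_seed = seed,
    predictors = cfg$predictors %||% consent_predictors(),
    proper = cfg$proper %||% TRUE, alpha = alpha,
    caliper = cfg$caliper, pool_untested = cfg$pool_untested %||% FALSE
  )
  if (isTRUE(report$nothing_to_impute)) {
    .write_manifest(out_dir, "pipeline", seed, config = cfg, inputs = input,
                    extra = list(note = "nothing to impute; bias = 0"))
    return(invisible(report))
  }
  write_study_table(report$consent_model$summary,
                    file.path(out_dir, "propensity_model.csv"), seed = seed)
  write_imputed_runs(report$imputed_runs,
                     file.path(out_dir, "imputed_runs.csv"), seed = seed)
  write_subsample_runs(c(report$bootstrap_runs, report$psm_runs),
                       file.path(out_dir, "subsamples.csv"), seed = seed)
  write_study_table(report$summary$summary,
                    file.path(out_dir, "group_summary.csv"), seed = seed)
  write_study_table(report$comparisons,
                    file.path(out_dir, "comparisons.csv"), seed = seed)
  write_study_table(report$population,
                    file.path(out_dir, "population_estimates.csv"),
                    seed = seed)
  comp <- composite_scores(
    as.data.frame(report$summary$empirical)[, test_measures()])
  write_study_table(attr(comp, "reference_params"),
                    file.path(out_dir, "composite_reference.csv"), seed = seed)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "bias_report.txt"))
  .write_manifest(out_dir, "pipeline", seed, config = cfg, inputs = input,
                  extra = list(
                    m = m, alpha = alpha,
                    n_participating = report$n_participating,
                    n_not_participating = report$n_not_participating,
                    consent_rate_percent = consent_rate(records)$percent,
                    nagelkerke_r2 = report$consent_model$nagelkerke_r2))
  invisible(report)
}

#' Run the false-missingness cross-validation end-to-end
#'
#' @param input Path to a study table.
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param m Runs (default 100).
#' @param factor,level,fraction See [false_missing_crossval()].
#' @param config Optional YAML/JSON override file.
#' @return The `crossval_report`, invisibly.
#' @export
run_crossval <- function(input, out_dir, seed, m = 100,
                         factor = "child_gender", level = "male",
                         fraction = 0.5, config = NULL) {
  cfg <- .read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_study_table(input, window = cfg$window %||% 300,
                              age_range = cfg$age_range %||% c(2, 8))
  report <- false_missing_crossval(
    records, factor = cfg$factor %||% factor, level = cfg$level %||% level,
    fraction = cfg$fraction %||% fraction, m = m, master_seed = seed,
    predictors = cfg$predictors %||% consent_predictors(),
    proper = cfg$proper %||% TRUE
  )
  write_study_table(report$table, file.path(out_dir, "crossval_report.csv"),
                    seed = seed)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "crossval_report.txt"))
  .write_manifest(out_dir, "crossval", seed, config = cfg, inputs = input,
                  extra = list(m = m, n_left_out = report$n_left_out))
  invisible(report)
}
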