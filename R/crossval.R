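# False-missingness cross-validation: delete known outcomes for a subgroup
# defined by an outcome-independent factor, recover them with the
# imputation and matching machinery, and compare recovered to observed
# statistics. The masked dyads' true outcomes are never visible to any
# fitting step; they re-enter only in the final comparison.

#' False-missingness cross-validation
#'
#' Selects `round(fraction * n)` participating dyads at the given factor
#' level (default: half of the boys), masks their test outcomes, refits
#' the imputation models on the remaining participants, imputes the masked
#' dyads over `m` runs, runs propensity-score matching of the remaining
#' participants against the masked set, and compares the recovered to the
#' observed statistics per measurement. The 95% interval of the simulated
#' group mean is the 2.5--97.5 percentile band of run means; a
#' normal-approximation band is reported alongside.
#'
#' @param records A `dyad_table`.
#' @param factor Covariate defining the subgroup (default `"child_gender"`).
#' @param level Factor level to mask within (default `"male"`).
#' @param fraction Fraction of that level's participants to mask
#'   (default 0.5).
#' @param m Imputation/matching runs (default 100).
#' @param master_seed Integer master seed.
#' @param predictors Imputation/propensity predictors.
#' @param proper Proper multiple imputation?
#' @return A `crossval_report`: per-measurement observed mean/SD of the
#'   left-out subgroup, simulated grand mean with percentile and normal
#'   95% bands, coverage flag, Cohen's d of observed vs pooled simulated
#'   member values, run-mean-level and member-level simulated SDs, and the
#'   PSM-arm grand mean.
#' @export
false_missing_crossval <- function(records, factor = "child_gender",
                                   level = "male", fraction = 0.5, m = 100,
                                   master_seed,
                                   predictors = consent_predictors(),
                                   proper = TRUE) {
  if (fraction <= 0 || fraction > 1) {
    stop("parameter error: fraction must be in (0, 1]", call. = FALSE)
  }
  part <- participation_groups(records)$participating
  if (!factor %in% names(part)) {
    stop("parameter error: unknown factor ", factor, call. = FALSE)
  }
  at_level <- as.character(part[[factor]]) == level
  if (!any(at_level)) {
    stop("parameter error: factor level absent: ", level, call. = FALSE)
  }
  n_out <- round(fraction * sum(at_level))
  set.seed(.derive_run_seed(master_seed, 0L))
  left_out_ids <- sample(part$dyad_id[at_level], n_out)
  masked <- part$dyad_id %in% left_out_ids
  training <- part[!masked, , drop = FALSE]
  if (nrow(training) <= length(predictors) + 1L) {
    stop("training set too small to fit the imputation models", call. = FALSE)
  }
  # masked view: outcome columns dropped so no fitting step can read them
  targets <- as.data.frame(part[masked, , drop = FALSE])
  observed <- targets[, c("dyad_id", test_measures())]
  targets <- targets[, setdiff(names(targets), test_measures())]

  imp_models <- fit_imputation_models(training, predictors = predictors)
  runs <- multiple_impute(imp_models, targets, m = m,
                          master_seed = master_seed, proper = proper)

  # PSM arm: propensity of being in the training (non-masked) set
  pseudo <- as.data.frame(part)
  pseudo$status <- ifelse(masked, "refused", "tested")
  for (col in test_measures()) pseudo[[col]][masked] <- NA_real_
  pseudo <- as_dyad_table(pseudo, window = attr(records, "window") %||% 300,
                          age_range = range(pseudo$child_age) + c(-0.5, 0.5))
  psm_runs <- tryCatch({
    pm <- fit_consent_model(pseudo, predictors = predictors)
    sc <- propensity_scores(pm, pseudo)
    psm_groups(training, targets, sc, m = m, master_seed = master_seed)
  }, error = function(e) {
    warning("PSM arm skipped: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  psm_vals <- if (!is.null(psm_runs)) {
    subsample_outcomes(psm_runs, training)
  } else NULL

  rows <- lapply(test_measures(), function(meas) {
    run_means <- vapply(runs, function(r) mean(r[[meas]]), 0)
    run_sds <- vapply(runs, function(r) stats::sd(r[[meas]]), 0)
    pooled <- unlist(lapply(runs, function(r) r[[meas]]), use.names = FALSE)
    obs <- observed[[meas]]
    qs <- stats::quantile(run_means, c(0.025, 0.975), names = FALSE, type = 7)
    se_norm <- stats::sd(run_means)
    d <- tryCatch(cohens_d(obs, pooled), error = function(e) {
      if (isTRUE(all.equal(mean(obs), mean(pooled)))) 0 else NA_real_
    })
    data.frame(
      measurement = meas,
      observed_mean = mean(obs), observed_sd = stats::sd(obs),
      sim_mean = mean(run_means),
      ci_lo = qs[1], ci_hi = qs[2],
      ci_lo_norm = mean(run_means) - 1.96 * se_norm,
      ci_hi_norm = mean(run_means) + 1.96 * se_norm,
      # tolerance keeps zero-width bands (degenerate, noiseless runs) from
      # failing on the last floating-point ulp
      covered = mean(obs) >= qs[1] - 1e-8 * max(1, abs(qs[1])) &
        mean(obs) <= qs[2] + 1e-8 * max(1, abs(qs[2])),
      d = d,
      sim_sd_member = stats::sd(pooled),
      sim_sd_run_mean = mean(run_sds),
      psm_mean = if (!is.null(psm_vals)) {
        mean(vapply(psm_vals, function(r) mean(r[[meas]]), 0))
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  structure(list(
    table = do.call(rbind, rows),
    factor = factor, level = level, fraction = fraction,
    left_out_ids = sort(left_out_ids), n_left_out = n_out,
    m = m, master_seed = master_seed, proper = proper
  ), class = "crossval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf(
    "False-missingness cross-validation: %d %s == %s participant(s) masked, m = %d\n",
    x$n_left_out, x$factor, x$level, x$m))
  cat(sprintf("Coverage: observed mean inside the 95%% band for %d/%d measurements; max |d| = %.3f\n",
              sum(x$table$covered), nrow(x$table), max(abs(x$table$d))))
  print(x$table[, c("measurement", "observed_mean", "sim_mean", "ci_lo",
                    "ci_hi", "covered", "d")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
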