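# Aggregation of the four group types (empirical, bootstrap, PSM, imputed)
# across runs, ensemble- and Rubin-level group comparisons, combined
# population estimates, and the bias of participant-only statistics.

.run_moments <- function(ensemble, outcomes) {
  # per-run mean and SD for each measurement, one row per (run, measurement)
  do.call(rbind, lapply(seq_along(ensemble), function(k) {
    r <- ensemble[[k]]
    data.frame(run = k, measurement = outcomes,
               mean = vapply(outcomes, function(m) mean(r[[m]]), 0),
               sd = vapply(outcomes, function(m) stats::sd(r[[m]]), 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Summarize empirical and ensemble groups
#'
#' Per-run means and SDs for each resampled/imputed ensemble, with the
#' grand mean and the SE across runs (SD of run means / sqrt(m)) per
#' measurement; the empirical group passes through as a single
#' realization with no SE.
#'
#' @param empirical Data frame of the participating group's member-level
#'   outcomes.
#' @param ensembles Named list of ensembles (each a list of per-run data
#'   frames), e.g. `list(bootstrap = ..., psm = ..., imputed = ...)`.
#' @param outcomes Measurement names summarized.
#' @return A `group_summary` object: tidy summary table plus the run-level
#'   statistics and the member-level values needed downstream.
#' @export
summarize_groups <- function(empirical, ensembles, outcomes = test_measures()) {
  stopifnot(is.list(ensembles), !is.null(names(ensembles)))
  for (ens in ensembles) {
    bad <- vapply(ens, function(r) !all(outcomes %in% names(r)), TRUE)
    if (any(bad)) stop("schema error: ensemble runs lack some measurements",
                       call. = FALSE)
    if (length(ens) < 2L) stop("need m >= 2 runs for an SE across runs",
                               call. = FALSE)
  }
  emp_tab <- data.frame(
    group_kind = "empirical", measurement = outcomes,
    grand_mean = vapply(outcomes, function(m) mean(empirical[[m]]), 0),
    grand_sd = vapply(outcomes, function(m) stats::sd(empirical[[m]]), 0),
    se_mean = NA_real_, sd_run_means = NA_real_, m_runs = 1L,
    row.names = NULL, stringsAsFactors = FALSE
  )
  run_stats <- list()
  ens_tabs <- lapply(names(ensembles), function(kind) {
    rs <- .run_moments(ensembles[[kind]], outcomes)
    rs$group_kind <- kind
    run_stats[[kind]] <<- rs
    m <- length(ensembles[[kind]])
    agg <- lapply(outcomes, function(meas) {
      mm <- rs$mean[rs$measurement == meas]
      ss <- rs$sd[rs$measurement == meas]
      data.frame(group_kind = kind, measurement = meas,
                 grand_mean = mean(mm), grand_sd = mean(ss),
                 se_mean = stats::sd(mm) / sqrt(m),
                 sd_run_means = stats::sd(mm), m_runs = m,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  structure(list(
    summary = rbind(emp_tab, do.call(rbind, ens_tabs)),
    run_stats = do.call(rbind, run_stats),
    empirical = empirical, ensembles = ensembles, outcomes = outcomes
  ), class = "group_summary")
}

.rubin_pool <- function(Q, U) {
  # Rubin's rules for a scalar estimand over m imputations:
  # total variance = within + (1 + 1/m) between, classic df
  m <- length(Q)
  Qbar <- mean(Q)
  Ubar <- mean(U)
  B <- stats::var(Q)
  T <- Ubar + (1 + 1 / m) * B
  if (B <= 0 || T <= 0) {
    df <- Inf
  } else {
    df <- (m - 1) * (1 + Ubar / ((1 + 1 / m) * B))^2
  }
  se <- sqrt(T)
  stat <- if (se > 0) Qbar / se else 0
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df)
       else 2 * stats::pnorm(-abs(stat))
  list(estimate = Qbar, se = se, df = df, p = p,
       within = Ubar, between = B)
}

#' Compare the group ensembles
#'
#' Per measurement: (i) the ensemble-level one-sample t of the imputed run
#' means against the empirical mean and two-sample t tests of PSM vs
#' bootstrap and PSM vs imputed run means -- these mirror the
#' SE-across-runs presentation but treat run means as data, so they
#' understate uncertainty; (ii) the Rubin's-rules pooled test of the
#' imputed-minus-empirical mean difference (within + between imputation
#' variance, small-sample df), the calibrated alternative; and (iii)
#' Cohen's d between the empirical member-level values and the imputed
#' member-level values pooled across runs. All tests are two-tailed.
#'
#' @param summary A `group_summary` from [summarize_groups()] containing
#'   `bootstrap`, `psm`, and `imputed` ensembles.
#' @param alpha Significance level for the flags (default 0.05).
#' @return Data frame, one row per measurement, with the statistics,
#'   p-values (`p_ensemble`, `p_rubin`, `p_psm_vs_boot`, `p_psm_vs_imp`),
#'   Cohen's d, and lower-than-empirical significance flags at `alpha`
#'   (`sig_lower_ensemble`, `sig_lower_rubin`).
#' @export
compare_groups <- function(summary, alpha = 0.05) {
  stopifnot(inherits(summary, "group_summary"))
  need <- c("bootstrap", "psm", "imputed")
  if (!all(need %in% names(summary$ensembles))) {
    stop("required group kinds missing: ",
         paste(setdiff(need, names(summary$ensembles)), collapse = ", "),
         call. = FALSE)
  }
  rs <- summary$run_stats
  emp <- summary$empirical
  n_emp <- nrow(emp)
  imputed <- summary$ensembles$imputed
  n_imp <- nrow(imputed[[1]])
  rows <- lapply(summary$outcomes, function(meas) {
    emp_vals <- emp[[meas]]
    emp_mean <- mean(emp_vals)
    pick <- function(kind, what) rs[[what]][rs$group_kind == kind &
                                              rs$measurement == meas]
    imp_means <- pick("imputed", "mean")
    imp_sds <- pick("imputed", "sd")
    psm_means <- pick("psm", "mean")
    boot_means <- pick("bootstrap", "mean")
    ens_t <- if (stats::sd(imp_means) > 0) {
      stats::t.test(imp_means, mu = emp_mean)
    } else list(statistic = 0, p.value = as.numeric(mean(imp_means) == emp_mean))
    rub <- .rubin_pool(Q = imp_means - emp_mean,
                       U = imp_sds^2 / n_imp + stats::var(emp_vals) / n_emp)
    safe_t <- function(a, b) {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      }
      stats::t.test(a, b)$p.value
    }
    pooled_imp <- unlist(lapply(imputed, function(r) r[[meas]]),
                         use.names = FALSE)
    d <- tryCatch(cohens_d(emp_vals, pooled_imp), error = function(e) NA_real_)
    data.frame(
      measurement = meas,
      empirical_mean = emp_mean,
      imputed_mean = mean(imp_means),
      d_empirical_vs_imputed = d,
      p_ensemble = ens_t$p.value,
      p_rubin = rub$p,
      rubin_se = rub$se,
      p_psm_vs_boot = safe_t(psm_means, boot_means),
      p_psm_vs_imp = safe_t(psm_means, imp_means),
      sig_lower_ensemble = ens_t$p.value < alpha & mean(imp_means) < emp_mean,
      sig_lower_rubin = rub$p < alpha & rub$estimate < 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Combined-population estimates and participant-only bias
#'
#' Per run, pools the empirical participating members with that run's
#' imputed not-participating members and computes the combined mean and
#' SD; the population estimate is the grand mean of these across runs,
#' with the SE across runs and, for the mean, the Rubin's-rules total
#' variance. Bias is the participant-only statistic minus the population
#' estimate: positive mean bias means the participants alone overestimate
#' performance; negative SD bias means they underestimate individual
#' differences.
#'
#' @param empirical Data frame of participating member-level outcomes.
#' @param imputed_runs `imputed_runs` list (one data frame per run).
#' @param outcomes Measurement names.
#' @return Data frame per measurement: population mean/SD with SEs,
#'   empirical mean/SD, `bias_mean`, `bias_sd`; run-level combined
#'   statistics attached as attribute `"runs"`.
#' @export
population_estimate <- function(empirical, imputed_runs,
                                outcomes = test_measures()) {
  n_p <- nrow(empirical)
  if (n_p < 1L || length(imputed_runs) < 1L ||
      nrow(imputed_runs[[1]]) < 1L) {
    stop("parameter error: empty group", call. = FALSE)
  }
  m <- length(imputed_runs)
  per_run <- do.call(rbind, lapply(seq_len(m), function(k) {
    r <- imputed_runs[[k]]
    do.call(rbind, lapply(outcomes, function(meas) {
      pooled <- c(empirical[[meas]], r[[meas]])
      data.frame(run = k, measurement = meas, n = length(pooled),
                 mean = mean(pooled), sd = stats::sd(pooled),
                 stringsAsFactors = FALSE)
    }))
  }))
  rows <- lapply(outcomes, function(meas) {
    pm <- per_run$mean[per_run$measurement == meas]
    ps <- per_run$sd[per_run$measurement == meas]
    n_tot <- per_run$n[per_run$measurement == meas][1]
    rub <- .rubin_pool(Q = pm, U = ps^2 / n_tot)
    data.frame(
      measurement = meas, n_population = n_tot,
      pop_mean = mean(pm), pop_mean_se = stats::sd(pm) / sqrt(m),
      pop_mean_sd_runs = stats::sd(pm), pop_mean_se_rubin = rub$se,
      pop_sd = mean(ps), pop_sd_se = stats::sd(ps) / sqrt(m),
      empirical_mean = mean(empirical[[meas]]),
      empirical_sd = stats::sd(empirical[[meas]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$bias_mean <- out$empirical_mean - out$pop_mean
  out$bias_sd <- out$empirical_sd - out$pop_sd
  attr(out, "runs") <- per_run
  out
}

#' Estimate consent bias end-to-end
#'
#' The package's main entry point: splits the table into participating
#' (tested) and not-participating (refused) groups, fits the consent
#' propensity model, fits per-outcome imputation models on the
#' participants, imputes the non-participants' would-be outcomes over `m`
#' runs, builds size-matched bootstrap and propensity-matched reference
#' ensembles, and reports group comparisons, population estimates, and the
#' bias of participant-only statistics.
#'
#' @param records A `dyad_table`.
#' @param m Runs per ensemble (default 100).
#' @param master_seed Integer master seed governing every random draw.
#' @param predictors Consent-model/imputation predictors (default the
#'   seven observational measurements).
#' @param proper Proper multiple imputation (default) or plug-in draws.
#' @param alpha Significance level.
#' @param caliper Optional PSM caliper (logit-SD units).
#' @param pool_untested Pool consented-untested dyads into the
#'   not-participating group?
#' @return A `bias_report` object (consent model, group summary,
#'   comparison table, population/bias table, and the ensembles).
#' @export
estimate_consent_bias <- function(records, m = 100, master_seed,
                                  predictors = consent_predictors(),
                                  proper = TRUE, alpha = 0.05,
                                  caliper = NULL, pool_untested = FALSE) {
  groups <- participation_groups(records, pool_untested = pool_untested)
  part <- groups$participating
  np <- groups$not_participating
  if (nrow(np) == 0L) {
    message("nothing to impute: no not-participating dyads; bias is 0")
    return(structure(list(empirical = part, nothing_to_impute = TRUE,
                          m = m, master_seed = master_seed),
                     class = "bias_report"))
  }
  model <- fit_consent_model(records, predictors = predictors)
  scores <- propensity_scores(model, rbind(as.data.frame(part),
                                           as.data.frame(np)))
  imp_models <- fit_imputation_models(part, predictors = predictors)
  imputed <- multiple_impute(imp_models, np, m = m,
                             master_seed = master_seed, proper = proper)
  boot <- bootstrap_groups(part, group_size = nrow(np), m = m,
                           master_seed = master_seed)
  psm <- psm_groups(part, np, scores, m = m, master_seed = master_seed,
                    caliper = caliper)
  ensembles <- list(
    bootstrap = subsample_outcomes(boot, part),
    psm = subsample_outcomes(psm, part),
    imputed = imputed
  )
  emp_out <- as.data.frame(part)[, c("dyad_id", test_measures())]
  summ <- summarize_groups(emp_out, ensembles)
  comp <- compare_groups(summ, alpha = alpha)
  pop <- population_estimate(emp_out, imputed)
  structure(list(
    consent_model = model, propensity = scores, imputation_models = imp_models,
    imputed_runs = imputed, bootstrap_runs = boot, psm_runs = psm,
    summary = summ, comparisons = comp, population = pop,
    n_participating = nrow(part), n_not_participating = nrow(np),
    m = m, master_seed = master_seed, alpha = alpha, proper = proper,
    nothing_to_impute = FALSE
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  if (isTRUE(x$nothing_to_impute)) {
    cat("Consent-bias report: no not-participating dyads; bias = 0\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Consent-bias report: %d participating, %d not participating, m = %d runs\n",
    x$n_participating, x$n_not_participating, x$m))
  cat(sprintf("Consent model Nagelkerke R^2 = %.3f\n",
              x$consent_model$nagelkerke_r2))
  cat("\nGroup comparisons (imputed vs empirical):\n")
  print(x$comparisons[, c("measurement", "empirical_mean", "imputed_mean",
                          "d_empirical_vs_imputed", "p_ensemble", "p_rubin",
                          "sig_lower_ensemble", "sig_lower_rubin")],
        row.names = FALSE, digits = 3)
  cat("\nPopulation estimates and participant-only bias:\n")
  print(x$population[, c("measurement", "pop_mean", "pop_sd",
                         "bias_mean", "bias_sd")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
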