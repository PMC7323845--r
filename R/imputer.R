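# Per-outcome predictive models fitted on the participating group, and
# stochastic (proper or plug-in) imputation of the not-participating
# group's would-be test outcomes over m independent runs.

.derive_run_seed <- function(master_seed, k) {
  # counter-based mix of (master_seed, run_index); both factors fit in
  # double-precision integer arithmetic (< 2^53) before the modulus
  a <- as.double(as.integer(master_seed) %% 2147483647L)
  as.integer((a * 48271 + as.double(k) * 1299721) %% 2147483646) + 1L
}

#' Fit per-outcome imputation models on the participating group
#'
#' One predictive model per test measurement, regressed on the
#' observational measurements: ordinary least squares for continuous
#' measurements (unbiased residual variance on n - p - 1 df) and logistic
#' regression for binary ones. Coefficient covariance (and, for the
#' gaussian family, the unscaled cross-product inverse) is retained so
#' that proper imputation can draw model parameters from their sampling
#' distribution. A binary measurement with no variation in the training
#' data is marked degenerate and imputed as its constant, with a warning.
#'
#' @param participating A `dyad_table` (or data frame) of tested dyads
#'   with complete outcomes.
#' @param outcomes Measurement names to model (default all seven).
#' @param predictors Predictor names (default the seven observational
#'   measurements).
#' @return An `imputation_models` object (list of per-measurement fits).
#' @export
fit_imputation_models <- function(participating, outcomes = test_measures(),
                                  predictors = obs_measures()) {
  df <- as.data.frame(participating)
  stopifnot(all(predictors %in% names(df)), all(outcomes %in% names(df)))
  X <- .predictor_matrix(df, predictors)
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p) {
    stop("underdetermined: n = ", n, " with ", p - 1L, " predictors",
         call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("collinearity error: aliased predictor(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  models <- lapply(outcomes, function(m) {
    y <- df[[m]]
    if (anyNA(y)) stop("missing outcome values in training data: ", m,
                       call. = FALSE)
    if (m %in% .binary_test_cols) {
      if (length(unique(y)) < 2L) {
        warning("binary outcome ", m, " constant in training data; ",
                "imputing the constant", call. = FALSE)
        return(list(family = "constant", value = y[1], n = n))
      }
      fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
      mu <- fit$fitted.values
      vc <- solve(crossprod(X, X * (mu * (1 - mu))))
      list(family = "binary-logistic",
           coefficients = stats::setNames(fit$coefficients, colnames(X)),
           vcov = vc, n = n)
    } else {
      if (n <= p) {
        stop("underdetermined: n = ", n, " with ", p - 1L, " predictors for ",
             m, call. = FALSE)
      }
      xtx_inv <- chol2inv(chol(crossprod(X)))
      beta <- drop(xtx_inv %*% crossprod(X, y))
      resid <- y - drop(X %*% beta)
      df_resid <- n - p
      sigma2 <- sum(resid^2) / df_resid
      list(family = "gaussian-linear",
           coefficients = stats::setNames(beta, colnames(X)),
           xtx_inv = xtx_inv, sigma2 = sigma2,
           df_resid = df_resid, n = n)
    }
  })
  names(models) <- outcomes
  structure(list(models = models, predictors = predictors,
                 outcomes = outcomes, n = n),
            class = "imputation_models")
}

.draw_mvnorm <- function(mean, sigma) {
  L <- chol(sigma)
  drop(mean + crossprod(L, stats::rnorm(length(mean))))
}

#' Impute one run of would-be outcomes
#'
#' Proper imputation (default) draws, for each gaussian measurement, a
#' residual variance from its scaled inverse-chi-square sampling
#' distribution, then coefficients from a normal centered at the estimates
#' with the rescaled covariance, then each outcome from the predictive
#' normal; binary measurements draw coefficients from their asymptotic
#' normal and outcomes as Bernoulli at the drawn-model probability. The
#' plug-in variant (`proper = FALSE`) fixes coefficients at the estimates,
#' adds gaussian noise at the point residual SD (none when the residual
#' variance is zero), and draws Bernoulli at the plug-in probability.
#' Imputed values are clipped to their valid ranges (counts >= 0,
#' nontarget functions <= 4, binaries already in support); the number of
#' clipped values is recorded.
#'
#' @param models An `imputation_models` object.
#' @param targets Dyads to impute (must carry all predictor values).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param proper Draw model parameters from their sampling distribution?
#' @param run_index Bookkeeping index stored on the result.
#' @return Data frame of `dyad_id` plus one column per imputed
#'   measurement, with attributes `seed`, `run_index`, and `clipped`
#'   (named clip counts).
#' @export
impute_run <- function(models, targets, seed, proper = TRUE, run_index = 1L) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("reproducibility error: impute_run requires an integer seed",
         call. = FALSE)
  }
  tdf <- as.data.frame(targets)
  miss <- !stats::complete.cases(tdf[, models$predictors, drop = FALSE])
  if (any(miss)) {
    stop("target dyad(s) missing predictor values: ",
         paste(tdf$dyad_id[miss], collapse = ", "), call. = FALSE)
  }
  X <- .predictor_matrix(tdf, models$predictors)
  set.seed(as.integer(seed))
  nt <- nrow(X)
  out <- data.frame(dyad_id = tdf$dyad_id, stringsAsFactors = FALSE)
  clipped <- stats::setNames(integer(length(models$outcomes)), models$outcomes)
  for (m in models$outcomes) {
    fit <- models$models[[m]]
    if (fit$family == "constant") {
      y <- rep(fit$value, nt)
    } else if (fit$family == "binary-logistic") {
      Xm <- X[, names(fit$coefficients), drop = FALSE]
      beta <- if (proper) .draw_mvnorm(fit$coefficients, fit$vcov)
              else fit$coefficients
      y <- stats::rbinom(nt, 1L, stats::plogis(drop(Xm %*% beta)))
    } else {
      Xm <- X[, names(fit$coefficients), drop = FALSE]
      if (proper) {
        sigma2 <- fit$sigma2 * fit$df_resid /
          stats::rchisq(1, df = fit$df_resid)
        beta <- if (sigma2 > 0)
          .draw_mvnorm(fit$coefficients, sigma2 * fit$xtx_inv)
        else fit$coefficients
      } else {
        sigma2 <- fit$sigma2
        beta <- fit$coefficients
      }
      y <- drop(Xm %*% beta) + stats::rnorm(nt, 0, sqrt(sigma2))
    }
    rng <- .test_ranges[[m]]
    if (!is.null(rng)) {
      yc <- pmin(pmax(y, rng[1]), rng[2])
      clipped[[m]] <- sum(yc != y)
      y <- yc
    }
    out[[m]] <- y
  }
  attr(out, "seed") <- as.integer(seed)
  attr(out, "run_index") <- as.integer(run_index)
  attr(out, "clipped") <- clipped
  out
}

#' Multiple imputation over m independent runs
#'
#' Runs [impute_run()] m times with per-run seeds derived deterministically
#' from `(master_seed, run_index)`, so the same master seed reproduces all
#' runs bit-for-bit.
#'
#' @param models An `imputation_models` object.
#' @param targets Dyads to impute.
#' @param m Number of runs (default 100).
#' @param master_seed Integer master seed.
#' @param proper Proper (parameter-drawing) imputation?
#' @return An `imputed_runs` list of per-run data frames, with a
#'   run-manifest data frame (`run_index`, `seed`) as attribute
#'   `"manifest"`.
#' @export
multiple_impute <- function(models, targets, m = 100, master_seed,
                            proper = TRUE) {
  if (m < 1) stop("parameter error: m must be >= 1", call. = FALSE)
  seeds <- vapply(seq_len(m), function(k) .derive_run_seed(master_seed, k), 1L)
  runs <- lapply(seq_len(m), function(k) {
    impute_run(models, targets, seed = seeds[k], proper = proper,
               run_index = k)
  })
  attr(runs, "manifest") <- data.frame(run_index = seq_len(m), seed = seeds)
  class(runs) <- c("imputed_runs", "list")
  runs
}

#' Persist imputed runs as one long-format table
#'
#' @param runs An `imputed_runs` object.
#' @param path Output path; the run manifest is written alongside as
#'   `<path>.manifest`.
#' @param seed Master seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_imputed_runs <- function(runs, path, seed = NULL) {
  long <- do.call(rbind, lapply(runs, function(r) {
    meas <- setdiff(names(r), "dyad_id")
    data.frame(run_index = attr(r, "run_index"),
               dyad_id = rep(r$dyad_id, times = length(meas)),
               measurement = rep(meas, each = nrow(r)),
               value = unlist(r[meas], use.names = FALSE))
  }))
  write_study_table(long, path, seed = seed)
  write_study_table(attr(runs, "manifest"), paste0(path, ".manifest"),
                    seed = seed)
  invisible(path)
}
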