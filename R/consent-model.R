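# Logistic regression of participation on observational measurements,
# Nagelkerke pseudo-R-squared, and propensity scores.

#' Predictor presets for the consent model
#'
#' `"observational"` uses the seven observational measurements;
#' `"extended"` adds the demographic covariates (child gender, parent
#' gender, group-composition flags, child age).
#'
#' @param preset One of `"observational"`, `"extended"`.
#' @return Character vector of predictor names.
#' @export
consent_predictors <- function(preset = c("observational", "extended")) {
  preset <- match.arg(preset)
  switch(preset,
         observational = .obs_cols,
         extended = c(.obs_cols, "child_gender", "parent_gender",
                      "other_adults_present", "other_children_present",
                      "child_age"))
}

.participation_outcome <- function(records,
                                   include_untested = c("drop", "agree")) {
  include_untested <- match.arg(include_untested)
  status <- as.character(records$status)
  keep <- status %in% c("tested", "refused") |
    (include_untested == "agree" & status == "consented_untested")
  records <- records[keep, , drop = FALSE]
  y <- as.integer(records$status != "refused")
  list(records = records, y = y)
}

.predictor_matrix <- function(records, predictors) {
  df <- as.data.frame(records)[, predictors, drop = FALSE]
  for (col in names(df)) if (is.character(df[[col]])) df[[col]] <- factor(df[[col]])
  stats::model.matrix(~ ., data = df)
}

# Newton-Raphson logistic fit with an optional ridge penalty on the slopes
# (never the intercept); used as the separation fallback.
.irls_logistic <- function(X, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + 2 * pen
    score <- crossprod(X, y - mu) - 2 * pen %*% beta
    beta <- beta + drop(solve(H, score))
    ll <- sum(y * eta - log1p(exp(eta))) - lambda * sum(beta[-1]^2)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(X, X * (mu * (1 - mu))) + 2 * pen
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov = solve(H), fitted = mu,
       loglik = sum(y * eta - log1p(exp(eta))), converged = converged)
}

#' Fit the consent (participation) logistic model
#'
#' Maximum-likelihood logistic regression with participation as the outcome
#' (tested = 1, refused = 0; consented-but-untested dyads are dropped by
#' default or counted as participating with `include_untested = "agree"`)
#' and the chosen predictors -- by default the seven observational
#' measurements on their raw scale. On detected separation (fitted
#' probabilities numerically at 0/1) the fit falls back, with a warning,
#' to a lightly ridge-penalized Newton solver (penalty on slopes only).
#'
#' @param records A `dyad_table`.
#' @param predictors Predictor column names (see [consent_predictors()]).
#' @param include_untested How to treat `consented_untested` dyads.
#' @param standardize Standardize continuous predictors before fitting?
#' @param ridge Ridge penalty on slopes (0 = plain ML; auto-set to 1e-4 on
#'   separation).
#' @return A `propensity_model`: coefficient table (estimate, SE, z, p),
#'   coefficient covariance, log-likelihoods of the fitted and
#'   intercept-only models, n, Nagelkerke R-squared, convergence flag.
#' @export
fit_consent_model <- function(records, predictors = consent_predictors(),
                              include_untested = c("drop", "agree"),
                              standardize = FALSE, ridge = 0) {
  po <- .participation_outcome(records, include_untested)
  keep <- stats::complete.cases(as.data.frame(po$records)[, predictors, drop = FALSE])
  if (any(!keep)) message("excluding ", sum(!keep),
                          " dyad(s) with missing predictors")
  rec <- po$records[keep, , drop = FALSE]
  y <- po$y[keep]
  if (length(unique(y)) < 2L) {
    stop("no-variation error: participation outcome is constant", call. = FALSE)
  }
  X <- .predictor_matrix(rec, predictors)
  scale_info <- NULL
  if (standardize) {
    cont <- setdiff(colnames(X), "(Intercept)")
    cont <- cont[apply(X[, cont, drop = FALSE], 2, function(v)
      length(unique(v)) > 2L)]
    scale_info <- list(center = colMeans(X[, cont, drop = FALSE]),
                       scale = apply(X[, cont, drop = FALSE], 2, stats::sd))
    X[, cont] <- scale(X[, cont, drop = FALSE], scale_info$center,
                       scale_info$scale)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("collinearity error: predictor matrix is rank deficient",
         call. = FALSE)
  }

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  separated <- any(fit$fitted.values > 1 - 1e-8 & y == 1) &&
    any(fit$fitted.values < 1e-8 & y == 0) ||
    any(abs(fit$coefficients) > 15)
  if (separated && ridge == 0) {
    warning("separation detected; refitting with ridge penalty 1e-4 on slopes",
            call. = FALSE)
    ridge <- 1e-4
  }
  if (ridge > 0) {
    fit2 <- .irls_logistic(X, y, lambda = ridge)
    coefs <- fit2$coefficients
    vc <- fit2$vcov
    ll_full <- fit2$loglik
    fitted <- fit2$fitted
    converged <- fit2$converged
  } else {
    coefs <- fit$coefficients
    eta <- drop(X %*% coefs)
    mu <- fit$fitted.values
    W <- mu * (1 - mu)
    vc <- solve(crossprod(X, X * W))
    ll_full <- sum(y * eta - log1p(exp(eta)))
    fitted <- mu
    converged <- fit$converged
  }
  if (!converged) {
    stop("convergence error: logistic fit did not converge", call. = FALSE)
  }
  n <- length(y)
  pbar <- mean(y)
  ll_null <- sum(y) * log(pbar) + (n - sum(y)) * log(1 - pbar)
  se <- sqrt(diag(vc))
  z <- coefs / se
  summary_tab <- data.frame(
    term = names(coefs), estimate = unname(coefs), se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  structure(list(
    predictor_names = predictors,
    coefficients = coefs, vcov = vc, summary = summary_tab,
    loglik_full = ll_full, loglik_null = ll_null, n = n,
    nagelkerke_r2 = nagelkerke_r2(ll_null, ll_full, n),
    converged = converged, ridge = ridge, standardize = standardize,
    scale_info = scale_info, fitted = stats::setNames(fitted, rec$dyad_id),
    n_positive = sum(y)
  ), class = "propensity_model")
}

#' Nagelkerke's pseudo-R-squared
#'
#' Cox--Snell R-squared `1 - exp(2 (ll0 - ll1) / n)` normalized by its
#' maximum attainable value `1 - exp(2 ll0 / n)`.
#'
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param loglik_full Log-likelihood of the fitted model.
#' @param n Number of observations.
#' @return A value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  stopifnot(n >= 1)
  if (loglik_full < loglik_null - 1e-8) {
    stop("loglik_full must be >= loglik_null", call. = FALSE)
  }
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom <= 0) stop("undefined: null log-likelihood is zero", call. = FALSE)
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  min(max(cox_snell / denom, 0), 1)
}

#' Propensity scores from a fitted consent model
#'
#' Inverse-logit of the linear predictor for each dyad. Dyads with missing
#' predictor values receive `NA` with a warning; others are unaffected.
#'
#' @param model A `propensity_model`.
#' @param records A `dyad_table` (any dyads, participating or not).
#' @return Named numeric vector of scores in (0, 1), named by `dyad_id`.
#' @export
propensity_scores <- function(model, records) {
  df <- as.data.frame(records)[, model$predictor_names, drop = FALSE]
  ok <- stats::complete.cases(df)
  scores <- rep(NA_real_, nrow(records))
  if (any(ok)) {
    X <- .predictor_matrix(records[ok, , drop = FALSE], model$predictor_names)
    absent <- setdiff(names(model$coefficients), colnames(X))
    if (length(absent) > 0L) {  # factor level unseen in this subset
      X <- cbind(X, matrix(0, nrow(X), length(absent),
                           dimnames = list(NULL, absent)))
    }
    X <- X[, names(model$coefficients), drop = FALSE]
    if (model$standardize && !is.null(model$scale_info)) {
      cont <- names(model$scale_info$center)
      X[, cont] <- scale(X[, cont, drop = FALSE], model$scale_info$center,
                         model$scale_info$scale)
    }
    scores[ok] <- stats::plogis(drop(X %*% model$coefficients))
  }
  if (any(!ok)) {
    warning("missing predictors; NA propensity for dyad(s): ",
            paste(records$dyad_id[!ok], collapse = ", "), call. = FALSE)
  }
  stats::setNames(scores, records$dyad_id)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf(
    "Consent model: n = %d (%d participating), Nagelkerke R^2 = %.3f\n",
    x$n, x$n_positive, x$nagelkerke_r2))
  cat(sprintf("log-likelihood %.3f (null %.3f)%s\n", x$loglik_full,
              x$loglik_null,
              if (x$ridge > 0) sprintf(", ridge = %g", x$ridge) else ""))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
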