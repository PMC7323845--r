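# Standardization, composite exploration scores, and the small inferential
# toolkit used throughout: partial correlation, Cohen's d, Fisher's exact.

#' Standardize values to z-scores
#'
#' Centers and scales by a reference mean and SD. Self-referenced (default)
#' standardization uses the sample mean and sample SD (n - 1 denominator)
#' of `x` itself, so the output has sample mean 0 and sample SD 1.
#'
#' @param x Numeric vector.
#' @param reference Optional `c(mean, sd)` reference; when supplied the
#'   transform is `(x - mean) / sd` with no length restriction on `x`.
#' @return Numeric vector of z-scores.
#' @export
zscore <- function(x, reference = NULL) {
  if (is.null(reference)) {
    if (length(x) < 2L) stop("need >= 2 values for self-referenced z-scores",
                             call. = FALSE)
    reference <- c(mean(x), stats::sd(x))
  }
  if (!is.finite(reference[2]) || reference[2] <= 0) {
    stop("degenerate scale: reference SD is zero or undefined", call. = FALSE)
  }
  (x - reference[1]) / reference[2]
}

#' Composite exploration scores
#'
#' Two composites per child: exploration variability, the sum of z-scores
#' of the whole-period test measurements, and exploration efficiency, the
#' sum of z-scores of the first-minute test measurements. Standardization
#' parameters (mean, SD per measurement) come from `reference` -- by
#' convention the participating group -- so imputed or matched children are
#' scored on the same scale as the empirical participants. Total play time
#' belongs to neither window and is excluded from both sets by default.
#'
#' @param outcomes Data frame of test measurements, one row per child.
#' @param reference Data frame supplying the standardization parameters
#'   (default: `outcomes` itself).
#' @param variability_set,efficiency_set Measurement names summed into each
#'   composite.
#' @return Data frame with columns `exploration_variability` and
#'   `exploration_efficiency`; the per-measurement reference `(mean, sd)`
#'   table is attached as attribute `"reference_params"`.
#' @export
composite_scores <- function(outcomes, reference = NULL,
                             variability_set = c("whole_target_activated",
                                                 "whole_unique_actions",
                                                 "whole_nontarget_functions"),
                             efficiency_set = c("first_target_activated",
                                                "first_unique_actions",
                                                "first_nontarget_functions")) {
  if (is.null(reference)) reference <- outcomes
  sets <- unique(c(variability_set, efficiency_set))
  missing_cols <- setdiff(sets, names(outcomes))
  if (length(missing_cols) > 0L) {
    stop("measurements absent from outcomes: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  params <- data.frame(
    measurement = sets,
    mean = vapply(sets, function(m) mean(reference[[m]]), 0),
    sd = vapply(sets, function(m) stats::sd(reference[[m]]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  degen <- !is.finite(params$sd) | params$sd <= 0
  if (any(degen)) {
    stop("degenerate reference SD for: ",
         paste(params$measurement[degen], collapse = ", "), call. = FALSE)
  }
  z <- function(m) {
    p <- params[params$measurement == m, ]
    (outcomes[[m]] - p$mean) / p$sd
  }
  sum_over <- function(set) {
    if (length(set) == 0L) return(rep(0, nrow(outcomes)))
    rowSums(vapply(set, z, numeric(nrow(outcomes))))
  }
  out <- data.frame(exploration_variability = sum_over(variability_set),
                    exploration_efficiency = sum_over(efficiency_set))
  attr(out, "reference_params") <- params
  out
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed (with intercept) on the control covariates; with no controls
#' this is the plain Pearson correlation. Rows with any missing value are
#' dropped case-wise.
#'
#' @param x,y Numeric vectors.
#' @param controls Data frame, matrix, or list of control covariates
#'   (may be empty or NULL).
#' @return List with `r`, `df` (= n - 2 - k), two-tailed `p` from the
#'   t transform, and `n` (rows used).
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || length(controls) == 0L) {
    cmat <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    cdf <- as.data.frame(controls)
    cmat <- stats::model.matrix(~ ., data = cdf)[, -1, drop = FALSE]
  }
  keep <- stats::complete.cases(x, y)
  if (ncol(cmat) > 0L) keep <- keep & stats::complete.cases(cmat)
  x <- x[keep]; y <- y[keep]; cmat <- cmat[keep, , drop = FALSE]
  n <- length(x); k <- ncol(cmat)
  if (n <= 2L + k) stop("need n > 2 + number of controls", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, cmat)
  if (qr(X)$rank < ncol(X)) {
    stop("collinearity error: control matrix is rank deficient", call. = FALSE)
  }
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) < 1e-14 || stats::sd(ry) < 1e-14) {
    stop("undefined correlation: constant residuals", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled SD computed from the
#' two sample variances on `n_a + n_b - 2` degrees of freedom.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return The standardized mean difference (positive when `group_a` is
#'   higher).
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("both groups need >= 2 values", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("degenerate scale: pooled SD is zero", call. = FALSE)
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Probability-mass rule: the p-value sums hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-tailed p-value.
#' @export
fishers_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8)) {
    stop("validation error: cells must be non-negative integers",
         call. = FALSE)
  }
  stats::fisher.test(round(tab))$p.value
}
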