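# -- column vocabularies ------------------------------------------------------

.status_levels <- c("not_invited", "refused", "consented_untested", "tested")

.covariate_cols <- c("site", "child_age", "child_gender", "parent_gender",
                     "other_adults_present", "other_children_present")

.obs_cols <- c("dyadic_time", "supervised_time", "unsupervised_time",
               "pedagogical_questions", "information_seeking_questions",
               "statements", "commands")

.test_cols <- c("total_play_time",
                "whole_target_activated", "whole_unique_actions",
                "whole_nontarget_functions",
                "first_target_activated", "first_unique_actions",
                "first_nontarget_functions")

.binary_test_cols <- c("whole_target_activated", "first_target_activated")

# valid ranges used for imputation clipping and validation
.test_ranges <- list(
  total_play_time           = c(0, Inf),
  whole_target_activated    = c(0, 1),
  whole_unique_actions      = c(0, Inf),
  whole_nontarget_functions = c(0, 4),
  first_target_activated    = c(0, 1),
  first_unique_actions      = c(0, Inf),
  first_nontarget_functions = c(0, 4)
)

#' Names of the observational measurements
#'
#' The seven pre-consent observational measurements coded for every dyad:
#' three interaction-duration measures (seconds within the observation
#' window) and four communication counts.
#'
#' @return Character vector of column names.
#' @export
obs_measures <- function() .obs_cols

#' Names of the test measurements
#'
#' The seven test-phase measurements, available only for tested dyads:
#' total play time plus three whole-period and three first-minute measures
#' (target-function activation, unique actions, nontarget functions out
#' of 4).
#'
#' @return Character vector of column names.
#' @export
test_measures <- function() .test_cols

#' @rdname test_measures
#' @export
binary_measures <- function() .binary_test_cols

.mandatory_cols <- function() {
  c("dyad_id", .covariate_cols, .obs_cols, "status")
}

# -- validation ---------------------------------------------------------------

#' Validate and classify a study table
#'
#' Checks a per-dyad data frame against the study-table contract: one row
#' per parent--child dyad carrying identifiers, demographic covariates, the
#' seven observational measurements, a participation status, and -- for
#' tested dyads only -- the seven test measurements.
#'
#' Invariants enforced: test outcomes present iff `status == "tested"`;
#' observational durations non-negative and summing to at most the
#' observation window; communication counts non-negative; child age within
#' `age_range`; binary test measures in \{0, 1\}; nontarget-function counts
#' in \[0, 4\]; first-minute cumulative counts no larger than their
#' whole-period counterparts. Violations raise errors naming the offending
#' `dyad_id`; rows with missing covariates are flagged with a warning and
#' kept (analyses exclude them case-wise).
#'
#' @param x A data frame with the study-table columns.
#' @param window Observation-window length in seconds (default 300).
#' @param age_range Plausible child-age bounds in years (default `c(2, 8)`).
#' @return `x` with status as a factor, classed `"dyad_table"`; the window
#'   is kept as an attribute.
#' @export
as_dyad_table <- function(x, window = 300, age_range = c(2, 8)) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.mandatory_cols(), names(x))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .test_cols) if (!col %in% names(x)) x[[col]] <- NA_real_
  if (anyDuplicated(x$dyad_id)) {
    stop("validation error: duplicated dyad_id: ",
         paste(unique(x$dyad_id[duplicated(x$dyad_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_status <- setdiff(unique(as.character(x$status)), .status_levels)
  if (length(bad_status) > 0L) {
    stop("validation error: unknown participation status: ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  x$status <- factor(as.character(x$status), levels = .status_levels)
  for (col in c("other_adults_present", "other_children_present")) {
    v <- x[[col]]
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v %in% c(0, 1, NA))) {
      stop("validation error: ", col, " must be coded 0/1", call. = FALSE)
    }
    x[[col]] <- as.integer(v)
  }

  .complain <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      stop("validation error: ", what, " (dyad_id: ",
           paste(x$dyad_id[which(bad)], collapse = ", "), ")", call. = FALSE)
    }
  }
  .complain(x$child_age < age_range[1] | x$child_age > age_range[2],
            sprintf("child_age outside [%g, %g]", age_range[1], age_range[2]))
  for (col in .obs_cols) .complain(x[[col]] < 0, paste0(col, " negative"))
  dur <- x$dyadic_time + x$supervised_time + x$unsupervised_time
  .complain(dur > window + 1e-6,
            sprintf("durations exceed observation window (%g s)", window))

  tested <- !is.na(x$status) & x$status == "tested"
  has_outcome <- rowSums(!is.na(as.matrix(x[, .test_cols]))) > 0L
  if (any(has_outcome & !tested)) {
    stop("consistency error: test outcomes present for non-tested dyad(s): ",
         paste(x$dyad_id[has_outcome & !tested], collapse = ", "),
         call. = FALSE)
  }
  if (any(tested & !complete.cases(x[, .test_cols]))) {
    stop("consistency error: tested dyad(s) with incomplete outcomes: ",
         paste(x$dyad_id[tested & !complete.cases(x[, .test_cols])],
               collapse = ", "), call. = FALSE)
  }
  for (col in .test_cols) {
    rng <- .test_ranges[[col]]
    .complain(x[[col]] < rng[1] | x[[col]] > rng[2],
              sprintf("%s outside [%g, %g]", col, rng[1], rng[2]))
  }
  for (col in .binary_test_cols) {
    .complain(!(x[[col]] %in% c(0, 1)) & !is.na(x[[col]]),
              paste0(col, " not in {0, 1}"))
  }
  .complain(x$first_unique_actions > x$whole_unique_actions + 1e-9,
            "first_unique_actions exceeds whole_unique_actions")
  .complain(x$first_nontarget_functions > x$whole_nontarget_functions + 1e-9,
            "first_nontarget_functions exceeds whole_nontarget_functions")

  incomplete <- !complete.cases(x[, c(.covariate_cols, .obs_cols)])
  if (any(incomplete)) {
    warning(sum(incomplete), " dyad(s) with missing covariates flagged; ",
            "analyses exclude them case-wise", call. = FALSE)
  }
  attr(x, "window") <- window
  attr(x, "incomplete_covariates") <- x$dyad_id[incomplete]
  class(x) <- c("dyad_table", "data.frame")
  x
}

# -- I/O ----------------------------------------------------------------------

#' Read a study table from delimited text
#'
#' Reads a comma-delimited, UTF-8 study table with a header row and
#' optional `#` comment lines, applies an optional column-name mapping,
#' and validates it with [as_dyad_table()]. If both raw coder columns
#' `<name>_coder1`/`<name>_coder2` are present for an observational
#' measurement and the averaged column is absent, they are averaged.
#'
#' @param path Path to the delimited text file.
#' @param col_map Optional named character vector mapping file column names
#'   to canonical names (`c(file_name = "canonical_name")`).
#' @param window,age_range Passed to [as_dyad_table()].
#' @return A `dyad_table`; an empty (header-only) file yields zero rows
#'   with a warning.
#' @export
read_study_table <- function(path, col_map = NULL, window = 300,
                             age_range = c(2, 8)) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       na.strings = c("", "NA"))
  if (!is.null(col_map)) {
    hit <- names(x) %in% names(col_map)
    names(x)[hit] <- unname(col_map[names(x)[hit]])
  }
  for (col in .obs_cols) {
    c1 <- paste0(col, "_coder1"); c2 <- paste0(col, "_coder2")
    if (!col %in% names(x) && all(c(c1, c2) %in% names(x))) {
      x[[col]] <- (x[[c1]] + x[[c2]]) / 2
      x[[c1]] <- x[[c2]] <- NULL
    }
  }
  if (nrow(x) == 0L) {
    warning("empty study table: ", path, call. = FALSE)
    for (col in setdiff(.mandatory_cols(), names(x))) x[[col]] <- character(0)
  }
  as_dyad_table(x, window = window, age_range = age_range)
}

#' Write a study table (or any result table) as delimited text
#'
#' Writes comma-delimited UTF-8 text with a leading `#` comment line
#' recording the tool version and, when given, the master seed, so every
#' output file is traceable to the run that produced it.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed Optional master seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path, seed = NULL) {
  ver <- as.character(utils::packageVersion("consentbias"))
  hdr <- sprintf("# consentbias %s%s", ver,
                 if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- derived quantities -------------------------------------------------------

#' Consent rate among invited dyads
#'
#' Proportion of invited dyads (status other than `not_invited`) that
#' agreed to participate (status `consented_untested` or `tested`).
#'
#' @param records A `dyad_table` or data frame with a `status` column.
#' @return List with `n_invited`, `n_agreed`, `proportion`, and `percent`
#'   (= 100 * proportion, unrounded).
#' @examples
#' # the recruitment arithmetic: 59 of 78 invited dyads agreed
#' tab <- synthetic_study_counts(n_tested = 47, n_untested = 12, n_refused = 19)
#' consent_rate(tab)$percent  # 75.641...
#' @export
consent_rate <- function(records) {
  status <- factor(as.character(records$status), levels = .status_levels)
  invited <- sum(status != "not_invited", na.rm = TRUE)
  if (invited == 0L) {
    stop("undefined consent rate: no invited dyads", call. = FALSE)
  }
  agreed <- sum(status %in% c("consented_untested", "tested"), na.rm = TRUE)
  p <- agreed / invited
  list(n_invited = invited, n_agreed = agreed,
       proportion = p, percent = 100 * p)
}

#' Split a study table into the two analysis groups
#'
#' The participating group comprises tested dyads; the not-participating
#' group comprises refusers. Consented-but-untested dyads are excluded
#' from both by default (set `pool_untested = TRUE` to pool them into the
#' not-participating group). Dyads with missing covariates are dropped
#' from both groups with a message.
#'
#' @param records A `dyad_table`.
#' @param pool_untested Pool `consented_untested` dyads into the
#'   not-participating group?
#' @return List with elements `participating` and `not_participating`.
#' @export
participation_groups <- function(records, pool_untested = FALSE) {
  bad <- records$dyad_id %in% attr(records, "incomplete_covariates")
  if (any(bad)) {
    message("excluding ", sum(bad), " dyad(s) with missing covariates")
    records <- records[!bad, , drop = FALSE]
  }
  np_status <- if (pool_untested) c("refused", "consented_untested") else "refused"
  list(participating = records[records$status == "tested", , drop = FALSE],
       not_participating = records[records$status %in% np_status, , drop = FALSE])
}

#' Minimal study table from recruitment counts
#'
#' Builds a schema-valid table whose only meaningful content is the
#' participation statuses, for recruitment-arithmetic checks such as the
#' consent rate; covariates are constant placeholders.
#'
#' @param n_tested,n_untested,n_refused,n_not_invited Status counts.
#' @return A `dyad_table`.
#' @export
synthetic_study_counts <- function(n_tested, n_untested = 0, n_refused = 0,
                                   n_not_invited = 0) {
  status <- rep(c("tested", "consented_untested", "refused", "not_invited"),
                c(n_tested, n_untested, n_refused, n_not_invited))
  n <- length(status)
  x <- data.frame(
    dyad_id = sprintf("d%03d", seq_len(n)), site = "site1", child_age = 4,
    child_gender = "female", parent_gender = "female",
    other_adults_present = 0L, other_children_present = 0L,
    dyadic_time = 100, supervised_time = 100, unsupervised_time = 100,
    pedagogical_questions = 1, information_seeking_questions = 1,
    statements = 1, commands = 1, status = status,
    stringsAsFactors = FALSE
  )
  tested <- status == "tested"
  for (col in .test_cols) x[[col]] <- ifelse(tested, 0, NA_real_)
  as_dyad_table(x)
}

#' @export
print.dyad_table <- function(x, ...) {
  cat(sprintf("Study table: %d dyads (%s)\n", nrow(x),
              paste(sprintf("%s=%d", levels(x$status), table(x$status)),
                    collapse = ", ")))
  NextMethod()
}
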