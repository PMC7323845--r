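# Reference ensembles drawn from the participating group: size-matched
# random subsamples (bootstrap groups) and propensity-score-matched
# subsamples the size of the not-participating group.

#' Size-matched bootstrap subsamples of the participating group
#'
#' Each run draws a uniform random subset, without replacement, of
#' `group_size` distinct participating dyads, so every run is a plausible
#' group of distinct children the size of the not-participating group.
#' Runs are independent given the derived per-run seed schedule.
#'
#' @param participating A `dyad_table` (or data frame) of tested dyads.
#' @param group_size Subsample size (the not-participating group's n).
#' @param m Number of runs (default 100).
#' @param master_seed Integer master seed.
#' @return A `subsample_runs` list; each element has `run_index`, `seed`,
#'   `kind = "bootstrap"`, and `member_ids`.
#' @export
bootstrap_groups <- function(participating, group_size, m = 100, master_seed) {
  ids <- as.character(participating$dyad_id)
  if (group_size > length(ids)) {
    stop("parameter error: group_size (", group_size,
         ") exceeds participating count (", length(ids), ")", call. = FALSE)
  }
  if (m < 1) stop("parameter error: m must be >= 1", call. = FALSE)
  runs <- lapply(seq_len(m), function(k) {
    seed <- .derive_run_seed(master_seed, k)
    set.seed(seed)
    list(run_index = k, seed = seed, kind = "bootstrap",
         member_ids = sample(ids, group_size))
  })
  class(runs) <- c("subsample_runs", "list")
  runs
}

#' One-to-one propensity-score matching without replacement
#'
#' Greedy nearest-neighbour matching on the logit of the propensity score:
#' not-participating dyads are processed in random order, and each is
#' matched to the nearest still-unmatched participating dyad; exact
#' distance ties are broken at random. The matched subsample therefore
#' equals the not-participating group in size as well as in propensity to
#' participate. With a caliper (in SD units of the logit scores), a
#' nearest neighbour beyond the caliper raises a matching-exhausted error
#' rather than returning a smaller group.
#'
#' @param participating,not_participating `dyad_table`s (or data frames).
#' @param scores Named propensity-score vector covering both groups
#'   (names = `dyad_id`), e.g. from [propensity_scores()].
#' @param seed Integer seed controlling processing order and tie-breaks.
#' @param caliper Optional caliper width in logit-score SD units.
#' @param run_index Bookkeeping index.
#' @return A run list with `run_index`, `seed`, `kind = "psm"`,
#'   `member_ids` (one match per not-participating dyad), and
#'   `mean_abs_distance` on the logit scale.
#' @export
psm_match <- function(participating, not_participating, scores, seed,
                      caliper = NULL, run_index = 1L) {
  p_ids <- as.character(participating$dyad_id)
  np_ids <- as.character(not_participating$dyad_id)
  if (length(np_ids) > length(p_ids)) {
    stop("matching-exhausted error: not-participating group larger than ",
         "participating group", call. = FALSE)
  }
  need <- c(p_ids, np_ids)
  if (!all(need %in% names(scores)) || anyNA(scores[need])) {
    stop("propensity scores missing for some dyads", call. = FALSE)
  }
  eps <- 1e-12
  lg <- stats::qlogis(pmin(pmax(scores[need], eps), 1 - eps))
  cal_width <- if (is.null(caliper)) Inf else caliper * stats::sd(lg)
  set.seed(as.integer(seed))
  order_np <- sample(np_ids)
  available <- p_ids
  matched <- character(0)
  dist_sum <- 0
  for (id in order_np) {
    d <- abs(lg[available] - lg[id])
    dmin <- min(d)
    if (dmin > cal_width) {
      stop("matching-exhausted error: no candidate within caliper for dyad ",
           id, call. = FALSE)
    }
    cand <- available[d <= dmin + eps]
    pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
    matched <- c(matched, pick)
    available <- setdiff(available, pick)
    dist_sum <- dist_sum + dmin
  }
  list(run_index = as.integer(run_index), seed = as.integer(seed),
       kind = "psm", member_ids = matched,
       mean_abs_distance = dist_sum / length(np_ids))
}

#' Ensemble of propensity-score-matched subsamples
#'
#' Repeats [psm_match()] `m` times with different random processing orders
#' (derived per-run seeds), yielding an ensemble comparable to the
#' bootstrap and imputed ensembles.
#'
#' @inheritParams psm_match
#' @param m Number of runs (default 100).
#' @param master_seed Integer master seed.
#' @return A `subsample_runs` list of `m` PSM runs.
#' @export
psm_groups <- function(participating, not_participating, scores, m = 100,
                       master_seed, caliper = NULL) {
  if (m < 1) stop("parameter error: m must be >= 1", call. = FALSE)
  runs <- lapply(seq_len(m), function(k) {
    psm_match(participating, not_participating, scores,
              seed = .derive_run_seed(master_seed, k + 500000L),
              caliper = caliper, run_index = k)
  })
  class(runs) <- c("subsample_runs", "list")
  runs
}

#' Member-level outcome values for subsample runs
#'
#' @param runs A `subsample_runs` list.
#' @param participating The `dyad_table` the members were drawn from.
#' @param outcomes Measurement names to extract.
#' @return List of per-run data frames (`dyad_id` + outcome columns).
#' @export
subsample_outcomes <- function(runs, participating,
                               outcomes = test_measures()) {
  df <- as.data.frame(participating)
  rownames(df) <- as.character(df$dyad_id)
  lapply(runs, function(r) {
    out <- df[r$member_ids, c("dyad_id", outcomes), drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Persist subsample membership as a long-format table
#'
#' @param runs A `subsample_runs` list.
#' @param path Output path.
#' @param seed Master seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_subsample_runs <- function(runs, path, seed = NULL) {
  long <- do.call(rbind, lapply(runs, function(r) {
    data.frame(run_index = r$run_index, kind = r$kind,
               dyad_id = r$member_ids, stringsAsFactors = FALSE)
  }))
  write_study_table(long, path, seed = seed)
}
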