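test_that("bootstrap subsamples are distinct-member, size-matched draws", {
  tab <- make_dyad_fixture(n_tested = 47, n_refused = 19, seed = 19)
  part <- participation_groups(tab)$participating
  runs <- bootstrap_groups(part, group_size = 19, m = 100, master_seed = 4)
  expect_length(runs, 100)
  for (r in runs[1:10]) {
    expect_length(r$member_ids, 19)
    expect_false(anyDuplicated(r$member_ids) > 0)
    expect_true(all(r$member_ids %in% part$dyad_id))
  }
  expect_gt(length(unique(vapply(runs, function(r)
    paste(sort(r$member_ids), collapse = ","), ""))), 90)

  # forced subset: group_size equal to the group returns the full group
  full <- bootstrap_groups(part, group_size = 47, m = 2, master_seed = 1)
  expect_setequal(full[[1]]$member_ids, part$dyad_id)
  expect_error(bootstrap_groups(part, group_size = 48, m = 1, master_seed = 1),
               "parameter")
})

test_that("bootstrap inclusion frequencies match the binomial expectation", {
  tab <- make_dyad_fixture(n_tested = 47, n_refused = 19, seed = 23)
  part <- participation_groups(tab)$participating
  m <- 400
  runs <- bootstrap_groups(part, group_size = 19, m = m, master_seed = 13)
  freq <- table(factor(unlist(lapply(runs, `[[`, "member_ids")),
                       levels = part$dyad_id)) / m
  p <- 19 / 47
  se <- sqrt(p * (1 - p) / m)
  expect_true(all(abs(freq - p) < 3.5 * se))
})

test_that("bootstrap run means are centered on the participating mean", {
  tab <- make_dyad_fixture(n_tested = 40, n_refused = 12, seed = 29)
  part <- participation_groups(tab)$participating
  runs <- bootstrap_groups(part, group_size = 12, m = 100, master_seed = 31)
  vals <- subsample_outcomes(runs, part)
  run_means <- vapply(vals, function(r) mean(r$total_play_time), 0)
  expect_lt(abs(mean(run_means) - mean(part$total_play_time)),
            3 * sd(run_means) / sqrt(100))
})

test_that("PSM matches exact propensity twins at distance zero", {
  tab <- make_dyad_fixture(n_tested = 10, n_refused = 1, seed = 37)
  part <- participation_groups(tab)$participating
  np <- participation_groups(tab)$not_participating
  # one participant shares the refuser's score exactly; all others are far
  scores <- setNames(c(seq(0.30, 0.74, length.out = 10), 0.12),
                     c(part$dyad_id, np$dyad_id))
  scores[part$dyad_id[4]] <- 0.12
  run <- psm_match(part, np, scores, seed = 3)
  expect_identical(run$member_ids, part$dyad_id[4])
  expect_equal(run$mean_abs_distance, 0)
})

test_that("PSM subsample tracks the not-participating propensity mean", {
  # clustered fixture: participants split into a high cluster and a low
  # cluster that overlaps the refusers; matching must pick the low cluster
  tab <- make_dyad_fixture(n_tested = 20, n_refused = 6, seed = 41)
  part <- participation_groups(tab)$participating
  np <- participation_groups(tab)$not_participating
  scores <- setNames(c(rep(0.85, 14), seq(0.25, 0.35, length.out = 6),
                       seq(0.26, 0.36, length.out = 6)),
                     c(part$dyad_id, np$dyad_id))
  run <- psm_match(part, np, scores, seed = 11)
  matched_mean <- mean(scores[run$member_ids])
  np_mean <- mean(scores[np$dyad_id])
  expect_lt(abs(matched_mean - np_mean),
            abs(mean(scores[part$dyad_id]) - np_mean))
  expect_length(run$member_ids, 6)
  expect_false(anyDuplicated(run$member_ids) > 0)
})

test_that("PSM is invariant to logit shifts and id relabeling", {
  tab <- make_dyad_fixture(n_tested = 15, n_refused = 5, seed = 43)
  part <- participation_groups(tab)$participating
  np <- participation_groups(tab)$not_participating
  set.seed(9)
  scores <- setNames(runif(20, 0.2, 0.9), c(part$dyad_id, np$dyad_id))
  run1 <- psm_match(part, np, scores, seed = 21)
  shifted <- plogis(qlogis(scores) + 1.3)
  run2 <- psm_match(part, np, shifted, seed = 21)
  expect_identical(run1$member_ids, run2$member_ids)

  relabel <- setNames(paste0("x_", names(scores)), names(scores))
  part2 <- as.data.frame(part); part2$dyad_id <- relabel[part2$dyad_id]
  np2 <- as.data.frame(np); np2$dyad_id <- relabel[np2$dyad_id]
  scores2 <- setNames(scores, relabel[names(scores)])
  run3 <- psm_match(part2, np2, scores2, seed = 21)
  expect_identical(run3$member_ids, unname(relabel[run1$member_ids]))
})

test_that("PSM never returns a silent partial match", {
  tab <- make_dyad_fixture(n_tested = 4, n_refused = 6, seed = 47)
  part <- participation_groups(tab)$participating
  np <- participation_groups(tab)$not_participating
  scores <- setNames(runif(10), c(part$dyad_id, np$dyad_id))
  expect_error(psm_match(part, np, scores, seed = 1), "matching-exhausted")

  # caliper: an out-of-reach refuser aborts rather than shrinking the group
  tab2 <- make_dyad_fixture(n_tested = 6, n_refused = 2, seed = 53)
  p2 <- participation_groups(tab2)$participating
  n2 <- participation_groups(tab2)$not_participating
  sc <- setNames(c(rep(0.9, 6), 0.88, 0.05), c(p2$dyad_id, n2$dyad_id))
  expect_error(psm_match(p2, n2, sc, seed = 2, caliper = 0.1),
               "matching-exhausted")
})

test_that("PSM ensembles vary the processing order but are seed-stable", {
  tab <- make_dyad_fixture(n_tested = 25, n_refused = 8, seed = 59)
  part <- participation_groups(tab)$participating
  np <- participation_groups(tab)$not_participating
  set.seed(101)
  scores <- setNames(runif(33, 0.2, 0.9), c(part$dyad_id, np$dyad_id))
  e1 <- psm_groups(part, np, scores, m = 10, master_seed = 61)
  e2 <- psm_groups(part, np, scores, m = 10, master_seed = 61)
  expect_identical(lapply(e1, `[[`, "member_ids"),
                   lapply(e2, `[[`, "member_ids"))
  expect_true(all(vapply(e1, function(r) length(r$member_ids) == 8, TRUE)))
})
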