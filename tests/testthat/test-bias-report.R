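# minimal one-measurement ensembles for arithmetic checks
tiny_runs <- function(means, n_members = 4, sd_within = 0) {
  lapply(seq_along(means), function(k) {
    vals <- means[k] + if (sd_within > 0) {
      v <- scale(rnorm(n_members))[, 1] * sd_within
      v
    } else rep(0, n_members)
    data.frame(dyad_id = paste0("t", seq_len(n_members)),
               total_play_time = means[k] + (vals - mean(vals)))
  })
}

test_that("group summaries aggregate run means and SEs as defined", {
  emp <- data.frame(dyad_id = paste0("e", 1:5),
                    total_play_time = c(1, 2, 3, 4, 5))
  ens <- list(imputed = tiny_runs(c(1, 3)), bootstrap = tiny_runs(c(2, 2)),
              psm = tiny_runs(c(2, 4)))
  s <- summarize_groups(emp, ens, outcomes = "total_play_time")
  imp <- s$summary[s$summary$group_kind == "imputed", ]
  # two runs with means 1 and 3: grand mean 2, SE = sd({1,3})/sqrt(2) = 1
  expect_equal(imp$grand_mean, 2)
  expect_equal(imp$se_mean, 1)
  boot <- s$summary[s$summary$group_kind == "bootstrap", ]
  expect_equal(boot$se_mean, 0)  # identical runs
  emp_row <- s$summary[s$summary$group_kind == "empirical", ]
  expect_equal(emp_row$grand_mean, 3)
  expect_true(is.na(emp_row$se_mean))
})

test_that("mismatched measurement sets raise a schema error", {
  emp <- data.frame(total_play_time = 1:4)
  ens <- list(imputed = list(data.frame(whole_unique_actions = 1:3),
                             data.frame(whole_unique_actions = 1:3)))
  expect_error(summarize_groups(emp, ens, outcomes = "total_play_time"),
               "schema")
})

test_that("an ensemble of constant run means at the empirical mean is null", {
  set.seed(31)
  emp <- data.frame(dyad_id = paste0("e", 1:6),
                    total_play_time = c(2, 4, 6, 8, 10, 12))
  ens <- list(imputed = tiny_runs(rep(mean(emp$total_play_time), 5),
                                  sd_within = 1),
              bootstrap = tiny_runs(rep(7, 5), sd_within = 1),
              psm = tiny_runs(rep(7, 5), sd_within = 1))
  s <- summarize_groups(emp, ens, outcomes = "total_play_time")
  comp <- compare_groups(s)
  expect_equal(comp$p_ensemble, 1)
  expect_false(comp$sig_lower_ensemble)
  expect_false(comp$sig_lower_rubin)
})

test_that("uniformly lower imputed runs trip the significance flags", {
  emp <- data.frame(dyad_id = paste0("e", 1:6),
                    total_play_time = c(10, 10.1, 9.9, 10, 10.05, 9.95))
  set.seed(7)
  low <- tiny_runs(9 + rnorm(20, 0, 0.01), n_members = 6, sd_within = 0.05)
  ens <- list(imputed = low, bootstrap = low, psm = low)
  comp <- compare_groups(summarize_groups(emp, ens,
                                          outcomes = "total_play_time"))
  expect_true(comp$sig_lower_ensemble)
  expect_true(comp$sig_lower_rubin)
  expect_gt(comp$d_empirical_vs_imputed, 0)
})

test_that("population estimates pool members with the weighted-mean identity", {
  # empirical mean 1 (n = 47), imputed mean 0 (n = 19), zero variance runs
  emp <- data.frame(dyad_id = paste0("e", 1:47),
                    total_play_time = rep(1, 47) + c(1e-9, rep(0, 46)))
  runs <- lapply(1:2, function(k)
    data.frame(dyad_id = paste0("n", 1:19), total_play_time = rep(0, 19)))
  pop <- population_estimate(emp, runs, outcomes = "total_play_time")
  expect_equal(pop$pop_mean, 47 / 66, tolerance = 1e-9)
  expect_equal(pop$bias_mean, 1 - 47 / 66, tolerance = 1e-9)
  expect_equal(pop$n_population, 66)
})

test_that("combined variance matches the two-group decomposition identity", {
  set.seed(17)
  emp <- data.frame(dyad_id = paste0("e", 1:12),
                    total_play_time = rnorm(12, 5, 2))
  runs <- lapply(1:4, function(k)
    data.frame(dyad_id = paste0("n", 1:7),
               total_play_time = rnorm(7, 3, 1.5)))
  pop <- population_estimate(emp, runs, outcomes = "total_play_time")
  per_run <- attr(pop, "runs")
  for (k in 1:4) {
    oracle <- combined_var_decomposition(emp$total_play_time,
                                         runs[[k]]$total_play_time)
    expect_equal(per_run$sd[per_run$run == k]^2, oracle, tolerance = 1e-10)
  }
  # equal within-group SDs with different means: combined SD exceeds both
  a <- rnorm(30); a <- (a - mean(a)) / sd(a)
  runs2 <- list(data.frame(dyad_id = paste0("n", 1:30),
                           total_play_time = a + 4),
                data.frame(dyad_id = paste0("n", 1:30),
                           total_play_time = a + 4))
  pop2 <- population_estimate(
    data.frame(dyad_id = paste0("e", 1:30), total_play_time = a),
    runs2, outcomes = "total_play_time")
  expect_gt(pop2$pop_sd, 1)
})

test_that("sign coherence: all-lower imputed runs give positive mean bias", {
  set.seed(23)
  emp <- data.frame(dyad_id = paste0("e", 1:10),
                    total_play_time = rnorm(10, 8))
  runs <- lapply(1:6, function(k)
    data.frame(dyad_id = paste0("n", 1:5),
               total_play_time = rnorm(5, 5)))
  run_means <- vapply(runs, function(r) mean(r$total_play_time), 0)
  stopifnot(all(run_means < mean(emp$total_play_time)))
  pop <- population_estimate(emp, runs, outcomes = "total_play_time")
  expect_gt(pop$bias_mean, 0)
})

test_that("empty groups are rejected", {
  emp <- data.frame(dyad_id = character(0), total_play_time = numeric(0))
  runs <- list(data.frame(dyad_id = "n1", total_play_time = 1))
  expect_error(population_estimate(emp, runs, outcomes = "total_play_time"),
               "parameter")
})

test_that("the end-to-end report is reproducible and structurally sound", {
  cfg <- synthetic_config(n_dyads = 120, seed = 3)
  obs <- observed_view(generate_population(cfg))
  r1 <- estimate_consent_bias(obs, m = 12, master_seed = 42)
  r2 <- estimate_consent_bias(obs, m = 12, master_seed = 42)
  expect_identical(r1$comparisons, r2$comparisons)
  expect_identical(r1$population, r2$population)
  expect_equal(nrow(r1$comparisons), 7)
  expect_equal(r1$population$n_population,
               rep(r1$n_participating + r1$n_not_participating, 7))
  # flags derive from the stored p-values at alpha
  expect_identical(r1$comparisons$sig_lower_rubin,
                   r1$comparisons$p_rubin < 0.05 &
                     r1$comparisons$imputed_mean < r1$comparisons$empirical_mean)
})

test_that("a table with no refusers reports nothing to impute", {
  tab <- make_dyad_fixture(n_tested = 15, n_refused = 0)
  expect_message(rep <- estimate_consent_bias(tab, m = 5, master_seed = 1),
                 "nothing to impute")
  expect_true(rep$nothing_to_impute)
})
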