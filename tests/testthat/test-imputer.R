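test_that("OLS fits solve the normal equations and flag degeneracies", {
  tab <- as.data.frame(make_dyad_fixture(n_tested = 6, n_refused = 0,
                                         seed = 12))
  preds <- c("pedagogical_questions", "commands")
  X <- cbind(1, as.matrix(tab[, preds]))
  y <- tab$total_play_time
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  models <- fit_imputation_models(tab, outcomes = "total_play_time",
                                  predictors = preds)
  fit <- models$models$total_play_time
  expect_equal(unname(fit$coefficients), unname(beta_oracle),
               tolerance = 1e-8)
  s2_oracle <- sum((y - X %*% beta_oracle)^2) / (6 - 3)
  expect_equal(fit$sigma2, s2_oracle, tolerance = 1e-8)

  # zero-residual relation: slope recovered exactly, residual variance 0
  det <- deterministic_training()
  m0 <- fit_imputation_models(det, outcomes = "total_play_time",
                              predictors = "pedagogical_questions")
  expect_equal(unname(m0$models$total_play_time$coefficients), c(0, 2),
               tolerance = 1e-8)
  expect_lt(m0$models$total_play_time$sigma2, 1e-16)

  # underdetermined: more parameters than rows
  tiny <- as.data.frame(make_dyad_fixture(n_tested = 5, n_refused = 0))
  expect_error(fit_imputation_models(tiny, outcomes = "total_play_time"),
               "underdetermined")
  # aliased predictors are named
  tab2 <- tab
  tab2$commands <- 2 * tab2$pedagogical_questions
  expect_error(fit_imputation_models(tab2, outcomes = "total_play_time",
                                     predictors = preds), "collinearity")
})

test_that("plug-in imputation is exact in the zero-residual limit", {
  det <- deterministic_training()
  models <- fit_imputation_models(det, outcomes = "total_play_time",
                                  predictors = "pedagogical_questions")
  target <- as.data.frame(det[1, ])
  target$pedagogical_questions <- 3
  imp <- impute_run(models, target, seed = 1, proper = FALSE)
  expect_equal(imp$total_play_time, 6)
  # proper draws collapse to the same point when the residual variance is 0
  imp_p <- impute_run(models, target, seed = 2, proper = TRUE)
  expect_equal(imp_p$total_play_time, 6, tolerance = 1e-9)
})

test_that("proper imputation is centered on the true conditional mean", {
  # Monte-Carlo oracle: average of imputed values over many runs
  set.seed(200)
  n <- 40
  tab <- as.data.frame(make_dyad_fixture(n_tested = n, n_refused = 0,
                                         seed = 61))
  tab$pedagogical_questions <- runif(n, 0, 4)
  tab$total_play_time <- pmax(0, 50 + 20 * tab$pedagogical_questions +
                                rnorm(n, 0, 5))
  tab <- as_dyad_table(tab)
  models <- fit_imputation_models(tab, outcomes = "total_play_time",
                                  predictors = "pedagogical_questions")
  target <- as.data.frame(tab[1, ])
  target$pedagogical_questions <- 2
  runs <- multiple_impute(models, target, m = 1000, master_seed = 303)
  vals <- vapply(runs, function(r) r$total_play_time, 0)
  fitted_mean <- sum(models$models$total_play_time$coefficients * c(1, 2))
  mc_se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - fitted_mean), 3 * mc_se + 0.02 * sd(vals))
})

test_that("binary imputation reproduces the fitted probability", {
  set.seed(77)
  n <- 60
  tab <- as.data.frame(make_dyad_fixture(n_tested = n, n_refused = 0,
                                         seed = 91))
  tab$whole_target_activated <- rbinom(n, 1, 0.5)
  tab$first_target_activated <- pmin(tab$first_target_activated,
                                     tab$whole_target_activated)
  tab <- as_dyad_table(tab)
  models <- fit_imputation_models(tab, outcomes = "whole_target_activated",
                                  predictors = "statements")
  targets <- as.data.frame(tab[1:2, ])
  runs <- multiple_impute(models, targets, m = 1000, master_seed = 5,
                          proper = FALSE)
  prop <- mean(vapply(runs, function(r) mean(r$whole_target_activated), 0))
  p_hat <- mean(plogis(drop(cbind(1, targets$statements) %*%
                              models$models$whole_target_activated$coefficients)))
  expect_lt(abs(prop - p_hat), 3 * sqrt(0.25 / 1000) + 0.02)
})

test_that("a constant binary training outcome is imputed as the constant", {
  tab <- as.data.frame(make_dyad_fixture(n_tested = 8, n_refused = 0,
                                         seed = 14))
  tab$whole_target_activated <- 1
  tab$first_target_activated <- pmin(tab$first_target_activated, 1)
  tab <- as_dyad_table(tab)
  expect_warning(models <- fit_imputation_models(
    tab, outcomes = "whole_target_activated",
    predictors = "pedagogical_questions"), "constant")
  imp <- impute_run(models, tab[1:3, ], seed = 4)
  expect_equal(imp$whole_target_activated, rep(1, 3))
})

test_that("multiple imputation is deterministic in the master seed", {
  tab <- make_dyad_fixture(n_tested = 20, n_refused = 6, seed = 44)
  part <- participation_groups(tab)$participating
  np <- participation_groups(tab)$not_participating
  models <- fit_imputation_models(part)
  r1 <- multiple_impute(models, np, m = 5, master_seed = 99)
  r2 <- multiple_impute(models, np, m = 5, master_seed = 99)
  expect_identical(r1[], r2[])
  r3 <- multiple_impute(models, np, m = 2, master_seed = 100)
  expect_false(identical(r1[[1]], r3[[1]]))
  # proper runs differ between themselves
  expect_false(identical(r1[[1]]$total_play_time, r1[[2]]$total_play_time))
  expect_equal(length(r1), 5)
  expect_error(multiple_impute(models, np, m = 0, master_seed = 1),
               "parameter")
  expect_error(impute_run(models, np, seed = NULL), "reproducibility")
})

test_that("proper draws add between-run variance over plug-in draws", {
  tab <- make_dyad_fixture(n_tested = 18, n_refused = 5, seed = 70)
  g <- participation_groups(tab)
  models <- fit_imputation_models(g$participating)
  vp <- vi <- numeric(0)
  proper <- multiple_impute(models, g$not_participating, m = 120,
                            master_seed = 8, proper = TRUE)
  plug <- multiple_impute(models, g$not_participating, m = 120,
                          master_seed = 8, proper = FALSE)
  v_of <- function(runs) var(vapply(runs, function(r)
    mean(r$total_play_time), 0))
  expect_gt(v_of(proper), v_of(plug))
})

test_that("clipping is rare on range-respecting synthetic data", {
  cfg <- synthetic_config(n_dyads = 400, seed = 21)
  obs <- observed_view(generate_population(cfg))
  g <- participation_groups(obs)
  models <- fit_imputation_models(g$participating)
  runs <- multiple_impute(models, g$not_participating, m = 30,
                          master_seed = 17)
  n_vals <- nrow(g$not_participating) * 30
  for (meas in c("whole_unique_actions", "first_unique_actions")) {
    clipped <- sum(vapply(runs, function(r) attr(r, "clipped")[[meas]], 0L))
    expect_lt(clipped / n_vals, 0.05)
  }
})

test_that("imputed runs persist as a long-format table with a manifest", {
  tab <- make_dyad_fixture(n_tested = 12, n_refused = 4, seed = 2)
  g <- participation_groups(tab)
  models <- fit_imputation_models(g$participating)
  runs <- multiple_impute(models, g$not_participating, m = 3, master_seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imputed_runs(runs, path, seed = 6)
  long <- read.csv(path, comment.char = "#")
  expect_equal(nrow(long), 3 * 4 * 7)
  expect_setequal(unique(long$measurement), test_measures())
  manifest <- read.csv(paste0(path, ".manifest"), comment.char = "#")
  expect_equal(manifest$run_index, 1:3)
})
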