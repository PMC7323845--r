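# Fixture builders and independent brute-force oracles shared across tests.

# a small, fully valid study table built in code
make_dyad_fixture <- function(n_tested = 6, n_refused = 3, n_untested = 0,
                              seed = 42) {
  set.seed(seed)
  n <- n_tested + n_refused + n_untested
  status <- rep(c("tested", "refused", "consented_untested"),
                c(n_tested, n_refused, n_untested))
  x <- data.frame(
    dyad_id = sprintf("f%03d", seq_len(n)),
    site = rep_len(c("zoo", "playground"), n),
    child_age = round(runif(n, 3, 6), 2),
    child_gender = rep_len(c("male", "female"), n),
    parent_gender = "female",
    other_adults_present = rbinom(n, 1, 0.3),
    other_children_present = rbinom(n, 1, 0.3),
    dyadic_time = round(runif(n, 20, 120), 1),
    supervised_time = round(runif(n, 20, 100), 1),
    unsupervised_time = round(runif(n, 10, 60), 1),
    pedagogical_questions = rpois(n, 1.5) + 0.5 * rbinom(n, 1, 0.5),
    information_seeking_questions = rpois(n, 2),
    statements = rpois(n, 10),
    commands = rpois(n, 4),
    status = status,
    stringsAsFactors = FALSE
  )
  tested <- status == "tested"
  whole_unique <- ifelse(tested, rpois(n, 8), NA)
  whole_nt <- ifelse(tested, pmin(rpois(n, 2), 4), NA)
  x$total_play_time <- ifelse(tested, round(runif(n, 60, 280), 1), NA)
  x$whole_target_activated <- ifelse(tested, rbinom(n, 1, 0.7), NA)
  x$whole_unique_actions <- whole_unique
  x$whole_nontarget_functions <- whole_nt
  x$first_target_activated <- ifelse(tested, x$whole_target_activated *
                                       rbinom(n, 1, 0.7), NA)
  x$first_unique_actions <- ifelse(tested, floor(whole_unique * 0.6), NA)
  x$first_nontarget_functions <- ifelse(tested, floor(whole_nt * 0.6), NA)
  as_dyad_table(x)
}

# brute-force two-tailed Fisher p by full enumeration of tables with the
# observed margins (probability-mass rule)
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_vals, function(a) {
    dhyper(a, r1, r2, c1)
  }, 0)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# coarse-to-fine grid search of the logistic log-likelihood; independent
# of the package's fitting route. A joint grid locates the basin, then
# cyclic coordinate-wise grid refinement (expand at edges, shrink inside)
# drives each coefficient to the concave log-likelihood's maximum.
logistic_grid_fit <- function(X, y, lower = -6, upper = 6, levels = 4,
                              grid_n = 11) {
  p <- ncol(X)
  ll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  center <- rep(0, p)
  width <- rep(upper - lower, p) / 2
  for (lev in seq_len(levels)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(center[j] - width[j], center[j] + width[j], length.out = grid_n)
    })
    combos <- as.matrix(expand.grid(grids))
    center <- combos[which.max(apply(combos, 1, ll)), ]
    width <- width * 0.5
  }
  w <- pmax(width, 0.5)
  best <- ll(center)
  for (sweep in 1:500) {
    old_best <- best
    for (j in seq_len(p)) {
      cand <- seq(center[j] - w[j], center[j] + w[j], length.out = 21)
      lls <- vapply(cand, function(b) {
        beta <- center; beta[j] <- b; ll(beta)
      }, 0)
      k <- which.max(lls)
      center[j] <- cand[k]
      best <- lls[k]
      w[j] <- if (k == 1L || k == 21L) w[j] * 2 else w[j] * 0.4
    }
    if (best - old_best < 1e-13 && all(w < 1e-7)) break
  }
  center
}

# participating group whose total_play_time is an exact linear function of
# pedagogical questions (zero residual)
deterministic_training <- function(n = 12, slope = 2) {
  tab <- as.data.frame(make_dyad_fixture(n_tested = n, n_refused = 0,
                                         seed = 55))
  tab$pedagogical_questions <- seq_len(n)
  tab$total_play_time <- slope * tab$pedagogical_questions
  as_dyad_table(tab)
}

# study table whose outcomes are exact linear functions of the
# observational measurements (noiseless), so plug-in recovery is exact
noiseless_table <- function(n_tested = 30, n_refused = 8, seed = 5) {
  set.seed(seed)
  tab <- as.data.frame(make_dyad_fixture(n_tested = n_tested,
                                         n_refused = n_refused, seed = seed))
  tested <- tab$status == "tested"
  pq <- tab$pedagogical_questions
  tab$total_play_time <- ifelse(tested, 60 + 10 * pq, NA)
  tab$whole_unique_actions <- ifelse(tested, 4 + 2 * pq, NA)
  tab$first_unique_actions <- ifelse(tested, 2 + pq, NA)
  tab$whole_nontarget_functions <- ifelse(tested, pmin(1 + 0.2 * pq, 4), NA)
  tab$first_nontarget_functions <- ifelse(tested, pmin(0.5 + 0.1 * pq, 4), NA)
  tab$whole_target_activated <- ifelse(tested, 1, NA)
  tab$first_target_activated <- ifelse(tested, 1, NA)
  as_dyad_table(tab)
}

# combined sample variance of two groups from the within/between
# decomposition, the oracle for the population-variance identity
combined_var_decomposition <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  ((na - 1) * var(a) + (nb - 1) * var(b) +
      na * nb / n * (mean(a) - mean(b))^2) / (n - 1)
}
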