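# Synthetic populations with known ground truth: covariates, consent
# decisions, and latent test outcomes for every dyad (including refusers),
# so each pipeline stage is testable against the truth.
#
# Missingness is MAR by construction: consent depends only on observed
# covariates (pedagogical questions and child gender), and latent outcomes
# depend only on covariates, so consent and outcomes are conditionally
# independent given the observed table.

.default_outcome_models <- function(coupling = 1) {
  # gaussian measurements: value = intercept + slope * PQ + N(0, sigma),
  # clipped to the valid range; binary: Bernoulli(plogis(int + slope * PQ));
  # first-minute measures are thinned from their whole-period counterparts
  list(
    total_play_time = list(family = "gaussian", intercept = 150,
                           pq_slope = 25 * coupling, sigma = 80),
    whole_target_activated = list(family = "binary", intercept = 0.2,
                                  pq_slope = 0.5 * coupling),
    whole_unique_actions = list(family = "gaussian", intercept = 9,
                                pq_slope = 1.2 * coupling, sigma = 4),
    whole_nontarget_functions = list(family = "gaussian", intercept = 2,
                                     pq_slope = 0.3 * coupling, sigma = 0.9),
    first_target_activated = list(family = "thinned-binary",
                                  parent = "whole_target_activated",
                                  retain_logit = 0.8),
    first_unique_actions = list(family = "thinned-gaussian",
                                parent = "whole_unique_actions",
                                fraction = 0.55, sigma = 1.5),
    first_nontarget_functions = list(family = "thinned-gaussian",
                                     parent = "whole_nontarget_functions",
                                     fraction = 0.6, sigma = 0.5)
  )
}

#' Configuration for the synthetic-population generator
#'
#' Defaults emulate the scale of a two-site field study: 78 dyads, ages
#' 3--6.3 years, a 300-second observation window with Dirichlet-composed
#' durations, over-dispersed (negative-binomial) communication counts, a
#' logistic consent model whose intercept is solved deterministically so
#' that the expected consent rate matches `consent_rate` (default 0.756),
#' and test-outcome models coupled to consent through the
#' pedagogical-question covariate. `coupling = 0` gives the null
#' configuration (consent carries no information about outcomes beyond
#' chance).
#'
#' @param n_dyads Number of dyads.
#' @param consent_rate Target marginal consent probability.
#' @param coupling Multiplier on the shared pedagogical-question slopes in
#'   both the consent and outcome models (1 = default coupling, 0 = null).
#' @param pq_consent_slope,gender_consent_slope Consent-model log-odds
#'   slopes (per pedagogical question; male vs female child).
#' @param outcome_models Per-measurement generative models (see source for
#'   the structure); defaults follow `coupling`.
#' @param count_params Negative-binomial `(mu, size)` per communication
#'   count (set `size = Inf` for pure Poisson).
#' @param duration_alpha Dirichlet concentration for the
#'   (dyadic, supervised, unsupervised) composition of the window.
#' @param duration_rest_alpha Concentration of the fourth, unallocated
#'   share of the window (transition time not attributed to any of the
#'   three coded activity types).
#' @param window Observation-window length in seconds.
#' @param age_range Child-age range (uniform draw), years.
#' @param site_probs Named site probabilities.
#' @param male_prob,parent_female_prob,other_adults_prob,other_children_prob
#'   Bernoulli parameters for the remaining covariates.
#' @param seed Default seed carried by the config (can be overridden at
#'   generation time).
#' @return A `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_dyads = 78, consent_rate = 0.756, coupling = 1,
                             pq_consent_slope = 0.8 * coupling,
                             gender_consent_slope = 0.7 * coupling,
                             outcome_models = .default_outcome_models(coupling),
                             count_params = list(
                               pedagogical_questions = c(mu = 1.2, size = 1.5),
                               information_seeking_questions = c(mu = 2.5, size = 2),
                               statements = c(mu = 12, size = 3),
                               commands = c(mu = 5, size = 2)),
                             duration_alpha = c(4, 3, 2),
                             duration_rest_alpha = 1.5, window = 300,
                             age_range = c(3, 6.3),
                             site_probs = c(zoo = 41 / 78, playground = 37 / 78),
                             male_prob = 0.5, parent_female_prob = 0.7,
                             other_adults_prob = 0.25,
                             other_children_prob = 0.35,
                             seed = NULL) {
  cfg <- list(n_dyads = n_dyads, consent_rate = consent_rate,
              coupling = coupling, pq_consent_slope = pq_consent_slope,
              gender_consent_slope = gender_consent_slope,
              outcome_models = outcome_models, count_params = count_params,
              duration_alpha = duration_alpha,
              duration_rest_alpha = duration_rest_alpha, window = window,
              age_range = age_range, site_probs = site_probs,
              male_prob = male_prob, parent_female_prob = parent_female_prob,
              other_adults_prob = other_adults_prob,
              other_children_prob = other_children_prob, seed = seed)
  .validate_synth_config(cfg)
  cfg$consent_intercept <- .solve_consent_intercept(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

.validate_synth_config <- function(cfg) {
  chk <- function(ok, field) {
    if (!ok) stop("invalid config field: ", field, call. = FALSE)
  }
  chk(is.numeric(cfg$n_dyads) && cfg$n_dyads >= 1, "n_dyads")
  chk(cfg$consent_rate > 0 && cfg$consent_rate < 1, "consent_rate")
  probs <- c(cfg$male_prob, cfg$parent_female_prob, cfg$other_adults_prob,
             cfg$other_children_prob, cfg$site_probs)
  chk(all(probs >= 0 & probs <= 1), "probabilities")
  chk(abs(sum(cfg$site_probs) - 1) < 1e-8, "site_probs")
  chk(all(cfg$duration_alpha > 0), "duration_alpha")
  chk(cfg$duration_rest_alpha > 0, "duration_rest_alpha")
  chk(cfg$window > 0, "window")
  chk(cfg$age_range[1] > 0 && cfg$age_range[2] > cfg$age_range[1], "age_range")
  for (nm in names(cfg$count_params)) {
    p <- cfg$count_params[[nm]]
    chk(p[["mu"]] > 0 && p[["size"]] > 0, nm)
  }
  for (nm in names(cfg$outcome_models)) {
    om <- cfg$outcome_models[[nm]]
    if (!is.null(om$sigma)) chk(om$sigma >= 0, paste0(nm, "$sigma"))
  }
  invisible(TRUE)
}

# Solve the consent-model intercept so that the expected consent rate over
# the (PQ count x child gender) distribution equals the target; the NB pmf
# makes this a deterministic finite sum, no simulation involved.
.solve_consent_intercept <- function(cfg) {
  p <- cfg$count_params$pedagogical_questions
  kmax <- max(50, stats::qnbinom(1 - 1e-10, mu = p[["mu"]], size = p[["size"]]))
  k <- 0:kmax
  wk <- stats::dnbinom(k, mu = p[["mu"]], size = p[["size"]])
  rate_at <- function(b0) {
    sum(wk * (cfg$male_prob *
                stats::plogis(b0 + cfg$pq_consent_slope * k +
                                cfg$gender_consent_slope) +
              (1 - cfg$male_prob) *
                stats::plogis(b0 + cfg$pq_consent_slope * k)))
  }
  stats::uniroot(function(b0) rate_at(b0) - cfg$consent_rate,
                 interval = c(-20, 20), tol = 1e-10)$root
}

.rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic population with known ground truth
#'
#' Draws covariates from the configured families, consent as
#' Bernoulli(inverse-logit of the consent model), and a latent test
#' outcome for every dyad (refusers included) from the outcome models;
#' gaussian outcomes are clipped to their valid ranges and first-minute
#' measures are thinned from whole-period ones so the ordering invariants
#' hold. Ground truth retained per dyad: the true consent probability and
#' the true (pre-clipping) conditional outcome means.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `synthetic_population` data frame: covariates, `consent`
#'   indicator, `latent_<measurement>` columns, `true_consent_prob`, and
#'   `true_mean_<measurement>` columns.
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) stop("reproducibility error: seed required", call. = FALSE)
  set.seed(as.integer(seed))
  n <- config$n_dyads
  rnb <- function(p) {
    if (is.infinite(p[["size"]])) stats::rpois(n, p[["mu"]])
    else stats::rnbinom(n, mu = p[["mu"]], size = p[["size"]])
  }
  # fourth share = unallocated time (transitions, uncodeable moments), so
  # the three coded durations sum to less than the window and are not an
  # exact linear function of each other
  shares <- .rdirichlet1(n, c(config$duration_alpha,
                              config$duration_rest_alpha)) * config$window
  pop <- data.frame(
    dyad_id = sprintf("syn%05d", seq_len(n)),
    site = sample(names(config$site_probs), n, replace = TRUE,
                  prob = config$site_probs),
    child_age = round(stats::runif(n, config$age_range[1],
                                   config$age_range[2]), 2),
    child_gender = ifelse(stats::rbinom(n, 1, config$male_prob) == 1,
                          "male", "female"),
    parent_gender = ifelse(stats::rbinom(n, 1, config$parent_female_prob) == 1,
                           "female", "male"),
    other_adults_present = stats::rbinom(n, 1, config$other_adults_prob),
    other_children_present = stats::rbinom(n, 1, config$other_children_prob),
    dyadic_time = shares[, 1], supervised_time = shares[, 2],
    unsupervised_time = shares[, 3],
    pedagogical_questions = rnb(config$count_params$pedagogical_questions),
    information_seeking_questions =
      rnb(config$count_params$information_seeking_questions),
    statements = rnb(config$count_params$statements),
    commands = rnb(config$count_params$commands),
    stringsAsFactors = FALSE
  )
  eta <- config$consent_intercept +
    config$pq_consent_slope * pop$pedagogical_questions +
    config$gender_consent_slope * (pop$child_gender == "male")
  pop$true_consent_prob <- stats::plogis(eta)
  pop$consent <- stats::rbinom(n, 1, pop$true_consent_prob)

  pq <- pop$pedagogical_questions
  latent <- list()
  for (mname in names(config$outcome_models)) {
    om <- config$outcome_models[[mname]]
    rng <- .test_ranges[[mname]]
    if (om$family == "gaussian") {
      mu <- om$intercept + om$pq_slope * pq
      y <- pmin(pmax(mu + stats::rnorm(n, 0, om$sigma), rng[1]), rng[2])
    } else if (om$family == "binary") {
      mu <- stats::plogis(om$intercept + om$pq_slope * pq)
      y <- stats::rbinom(n, 1, mu)
    } else if (om$family == "thinned-binary") {
      parent <- latent[[om$parent]]
      retain <- stats::plogis(om$retain_logit)
      mu <- attr(parent, "true_mean") * retain
      y <- parent * stats::rbinom(n, 1, retain)
    } else { # thinned-gaussian: fraction of the whole-period value + noise
      parent <- latent[[om$parent]]
      mu <- om$fraction * attr(parent, "true_mean")
      y <- pmin(pmax(om$fraction * parent + stats::rnorm(n, 0, om$sigma),
                     rng[1]), pmin(parent, rng[2]))
    }
    attr(y, "true_mean") <- mu
    latent[[mname]] <- y
  }
  for (mname in names(latent)) {
    pop[[paste0("latent_", mname)]] <- as.numeric(latent[[mname]])
    pop[[paste0("true_mean_", mname)]] <- attr(latent[[mname]], "true_mean")
  }
  attr(pop, "config") <- config
  attr(pop, "seed") <- as.integer(seed)
  class(pop) <- c("synthetic_population", "data.frame")
  pop
}

#' Project a synthetic population to its observed view
#'
#' Masks refusers' latent outcomes and assigns statuses (tested for
#' consenters, refused otherwise), yielding a valid study table that is
#' schema-indistinguishable from real data.
#'
#' @param population A `synthetic_population`.
#' @return A `dyad_table`.
#' @export
observed_view <- function(population) {
  stopifnot(inherits(population, "synthetic_population"))
  cfg <- attr(population, "config")
  x <- as.data.frame(population)
  x$status <- ifelse(x$consent == 1, "tested", "refused")
  for (mname in test_measures()) {
    x[[mname]] <- ifelse(x$consent == 1, x[[paste0("latent_", mname)]],
                         NA_real_)
  }
  keep <- c("dyad_id", .covariate_cols, .obs_cols, "status", test_measures())
  as_dyad_table(x[, keep], window = cfg$window,
                age_range = c(cfg$age_range[1] - 0.5, cfg$age_range[2] + 0.5))
}

#' Ground-truth selection effects of a synthetic population
#'
#' Compares consenters' and refusers' latent outcomes (which the observed
#' view hides): Cohen's d and mean/SD gaps per measurement, plus the true
#' population mean and SD -- the quantities the estimation pipeline tries
#' to recover.
#'
#' @param population A `synthetic_population`.
#' @return Data frame per measurement: `d`, `mean_gap`, `sd_gap`
#'   (consenters minus refusers), `pop_mean`, `pop_sd` (all dyads' latent
#'   values).
#' @export
true_bias <- function(population) {
  stopifnot(inherits(population, "synthetic_population"))
  cons <- population$consent == 1
  if (!any(cons) || all(cons)) {
    stop("parameter error: need both consenters and refusers", call. = FALSE)
  }
  rows <- lapply(test_measures(), function(mname) {
    y <- population[[paste0("latent_", mname)]]
    data.frame(
      measurement = mname,
      d = cohens_d(y[cons], y[!cons]),
      mean_gap = mean(y[cons]) - mean(y[!cons]),
      sd_gap = stats::sd(y[cons]) - stats::sd(y[!cons]),
      pop_mean = mean(y), pop_sd = stats::sd(y),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
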