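---
title: "Estimating selection bias from voluntary participation: methods"
author: "consentbias"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(consentbias)
```

## The problem

Developmental studies recruited in the field test only the children whose
parents consent. If the parenting practices that predict consent also
predict children's behaviour in the test, the tested sample is not a random
draw from the observed population: participant-only means and standard
deviations are biased estimates of what the full population would have
shown. `consentbias` quantifies that bias for designs in which a set of
*pre-consent observational covariates* is available for every dyad (here:
three interaction-duration measures and four communication counts coded
during a five-minute public observation) while the *test outcomes* (total
play time plus three whole-period and three first-minute exploration
measures) exist only for the tested dyads.

The central assumption is missing-at-random (MAR): conditional on the
observational covariates, a parent's consent decision carries no further
information about the child's would-be test outcome. Under MAR the
non-participants' outcomes can be imputed from models fitted on the
participants, and the combined (participating + imputed not-participating)
sample estimates the pre-consent population.

## The estimation pipeline

`estimate_consent_bias()` runs five stages.

1. **Group definition.** Participating = dyads with test data ("tested");
   not-participating = refusers. Dyads that consented but were never tested
   sit in neither group by default (`pool_untested = TRUE` pools them with
   the refusers). This keeps the imputed group the size of the refuser
   group, which is also the size every reference ensemble is matched to.
2. **Consent (propensity) model.** Logistic regression of participation on
   the seven observational measurements (optionally plus demographics,
   `consent_predictors("extended")`), fitted by maximum likelihood via
   `stats::glm`. Fit quality is reported as Nagelkerke's pseudo-R²,
   the Cox–Snell statistic normalized by its attainable maximum.
   Predictors enter on their raw scale so coefficients are log-odds per
   unit (per question, per second); `standardize = TRUE` switches to
   SD units. Quasi-separation — plausible at n ≈ 78 with seven
   predictors — triggers an automatic refit with a small ridge penalty
   (1e-4, slopes only) and a warning rather than silently exploding
   coefficients.
3. **Imputation models and proper multiple imputation.** One predictive
   model per test measurement, trained on participants only: OLS for
   continuous measurements, logistic for the two binary activation
   indicators (keeping draws inside the support rather than forcing a
   linear model onto a 0/1 outcome). Each of the `m = 100` runs draws, per
   continuous measurement, (i) a residual variance from its scaled
   inverse-χ² sampling distribution, (ii) coefficients from a normal
   centred at the estimates with the rescaled covariance, (iii) outcomes
   from the predictive normal; binary measurements draw coefficients from
   their asymptotic normal and outcomes as Bernoulli. This "proper"
   scheme makes the between-run spread reflect estimation uncertainty, not
   just residual noise; the plug-in variant (`proper = FALSE`) exists for
   tests and for the deterministic-recovery limit. Imputed values are
   clipped to valid ranges (counts ≥ 0, nontarget functions ≤ 4) with clip
   counts recorded; counts stay continuous until report time, because
   rounding before averaging biases group means.
4. **Reference ensembles.** Two ensembles of participant subsamples the
   size of the refuser group: *bootstrap* groups (uniform random subsets
   without replacement — sampling with replacement would duplicate
   children within a "group") and *PSM* groups (greedy 1:1
   nearest-neighbour matching on the logit propensity, refusers processed
   in random order, ties broken at random, no caliper by default so the
   size match is exact; a caliper in logit-SD units is available and
   aborts rather than returning a short group). The PSM match is re-run
   `m` times with fresh processing orders to give an ensemble comparable
   to the others.
5. **Aggregation and bias.** Per measurement the report gives grand means
   and SEs across runs for each ensemble, three comparisons (imputed vs
   empirical, PSM vs bootstrap, PSM vs imputed), Cohen's d between
   empirical members and imputed members pooled across runs, and the
   population estimate: per run, the n_p empirical values pooled with that
   run's n_np imputed values; across runs, the grand mean with its
   ensemble SE. Bias = participant-only statistic − population estimate,
   so positive mean bias reads as "participants alone overestimate
   performance" and negative SD bias as "underestimate individual
   differences".

### Two inferential readings, deliberately both reported

The ensemble-level t tests (`p_ensemble`) treat the `m` run means as data.
They mirror the error-bars-across-runs presentation, but their SE shrinks
with `m` — with enough runs any fixed difference becomes "significant", so
under a null coupling they fire far above the nominal rate. The report
therefore also pools by Rubin's rules (`p_rubin`): total variance = mean
within-run variance + (1 + 1/m) × between-run variance, with the classic
small-sample df. The Rubin flag (`sig_lower_rubin`) is the calibrated one;
the package's own null-calibration test checks it fires at no more than
the nominal α. Both columns are kept because they answer different
questions — "is the ensemble's location distinguishable from the empirical
mean" versus "is there evidence the two groups differ, accounting for all
sampling uncertainty".

## Composite scores

`composite_scores()` builds two composites per child: exploration
variability (sum of z-scores of the whole-period measures) and exploration
efficiency (sum of z-scores of the first-minute measures). Total play time
belongs to neither window cleanly, so the default sets are the symmetric
3 + 3 whole-period/first-minute trios with total play time reported
separately; both sets are arguments. Standardization parameters always
come from a stated reference group (default: the participants), so imputed
or matched children are scored on the same scale; binary measures are
z-scored like continuous ones. The supporting toolkit — `zscore`,
`partial_correlation` (residual correlation, df = n − 2 − k),
`cohens_d` (pooled-SD), `fishers_exact` (probability-mass two-tailed
rule) — reports p to machine precision with α = .05 two-tailed flags and
applies no multiplicity correction (a Holm flag is a one-liner away via
`stats::p.adjust` on the reported columns).

## False-missingness cross-validation

`false_missing_crossval()` validates the machinery on data where the truth
is known: it masks the outcomes of a random half of one gender's
participants (gender being a factor the outcomes do not depend on),
refits the imputation models on the rest, imputes the masked dyads over
`m` runs, re-runs PSM against the masked set, and compares recovered to
observed statistics. The masked dyads' outcomes are structurally invisible
to every fitting step — the target table simply lacks those columns — and
re-enter only in the final comparison table. The 95% interval of the
simulated group mean is the 2.5–97.5 percentile band of run means (the
normal-approximation band is reported alongside, since either convention
is defensible); coverage of zero-width bands is judged with a 1e-8
relative tolerance so the noiseless deterministic limit is recovered
exactly. Both member-level and run-mean-level SDs of the simulated group
are reported, as the two readings of "no systematic SD bias" differ.

## The synthetic-data generator

`synthetic_config()` + `generate_population()` create full populations
with ground truth: covariates, a consent decision, and a latent outcome
for *every* dyad, so `observed_view()` (which masks refusers' outcomes)
yields a pipeline input whose right answer is known via `true_bias()`.

Generator choices, fixed once:

* **Counts** (questions, statements, commands) are negative-binomial —
  non-negative and over-dispersed, as communication counts in short
  observation windows are; `size = Inf` degrades to Poisson. Defaults:
  pedagogical questions mu 1.2 (size 1.5), information-seeking 2.5,
  statements 12, commands 5.
* **Durations** are a Dirichlet composition of the 300-s window over
  (dyadic, supervised, unsupervised, unallocated) with concentrations
  (4, 3, 2, 1.5). The explicit unallocated share represents transition
  time no coder would attribute to an activity type; it also means the
  three coded durations are not an exact linear function of one another,
  which any design with all three durations plus an intercept in one
  model requires.
* **Consent** is logistic in pedagogical questions (slope 0.8) and child
  gender (male slope 0.7), with the intercept solved deterministically
  (finite NB-pmf sum + root finding, no simulation) so the expected
  consent rate hits the target, default 0.756. With all slopes zero the
  intercept is exactly logit(0.756) ≈ 1.13.
* **Outcomes** are coupled to consent only through pedagogical questions:
  e.g. whole-period unique actions = 9 + 1.2·PQ + N(0, 4), clipped to
  range (clipping is rare, < 5%, by construction); the binary target
  activation is Bernoulli(logit⁻¹(0.2 + 0.5·PQ)). First-minute measures
  are thinned versions of whole-period ones (fraction + noise, clipped to
  [0, whole]; binary retention draw), enforcing the cumulative-ordering
  invariants. `coupling = 0` zeroes every shared slope — the null world.
* **MAR holds by construction**: consent depends only on observed
  covariates, outcomes only on covariates, so consent ⊥ outcomes | table.

What the generator does *not* emulate: coder disagreement, site effects on
outcomes, outcome dependence on durations or the other counts,
non-ignorable (MNAR) refusal. Passing tests on this generator therefore
show the estimation machinery is correct *under MAR with a
correctly-specified outcome model*; they cannot show MAR holds in any real
data set.

## Problem sizes and numerical choices

The package's own calibration checks run at: null calibration and
sign/parameter recovery, 100 replicate populations of n = 500 with
m = 100; cross-validation coverage, 200 replicate populations of n = 200
with m = 100; Monte-Carlo oracles at m = 1000 on single targets. These
sizes put 3-binomial-SE bands around the nominal rates that are tight
enough to be informative while keeping each suite in minutes on one CPU.

Numerical details: sample SDs use n − 1 throughout; z-scoring a
zero-variance measurement is an error naming the measurement, never a
silent 0/0; logistic convergence is relative log-likelihood change
< 1e-10 or 100 iterations; per-run seeds derive from
(master seed, run index) by a fixed integer mix, so a master seed pins
every draw in the pipeline and runs are reproducible individually; PSM
distance ties (within 1e-12) are broken by the run's RNG; the
combined-population SD satisfies the exact two-group variance
decomposition, which the tests verify to 1e-10.

## Limitations

* Everything downstream of the consent model conditions on MAR; with
  outcome-dependent refusal the imputed group is biased toward the
  participants and the reported bias is a lower bound in spirit, not a
  guarantee.
* The imputation models are main-effects linear/logistic in the seven
  observational measurements; strong nonlinearity or interactions in the
  true outcome process would propagate into the imputed means.
* Ensemble-level significance counts should be read descriptively (see
  the two-readings section); the Rubin columns carry the inferential
  weight.
* Propensity matching is greedy without replacement; with poor overlap it
  degrades (large mean matched distance) before it errors. The mean
  absolute matched distance is reported per run for exactly this check.
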