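---
title: "Estimating drug-safety signals with propensity strata, empirical calibration and self-controlled case series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating drug-safety signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safetysignal)
```

safetysignal implements the estimation machinery of multi-database
observational drug-safety studies: new-user active-comparator cohorts with
large-scale propensity adjustment, negative-control empirical calibration, a
self-controlled case series (SCCS) estimator, and heterogeneity-gated
random-effects evidence synthesis. This vignette is the package's account of
the underlying models, the defaults and why they were chosen, what the
bundled simulator does and does not emulate, and the package's known
limitations.

## The estimation problem

Claims and EHR data record, per person, an observation period, dispensing
records (drug, start day, days supplied) and condition occurrences. From
these we want the hazard ratio (HR) of a severe adverse event among
initiators of a target drug relative to initiators of a clinically
exchangeable comparator. Two sources of error dominate: confounding by
indication and channeling (who gets which drug is not random), and residual
systematic error that survives covariate adjustment (coding differences,
unmeasured comorbidity). The package attacks the first with propensity-score
stratification and the second with negative-control calibration, and
cross-checks the cohort design with a within-person SCCS that is immune to
all time-invariant confounding.

## Cohort construction

**Drug eras.** Dispensing records are fragmented; persistent exposure is
reconstructed by merging consecutive records of the same drug when the
number of unexposed days between them (`next_start − previous_era_end − 1`)
is at most `max_gap_days` (default 90). The boundary is deliberately
specified on the *unexposed-day count*: a record ending day 29 merges with a
start on day 120 (gap 90) and splits from day 121 (gap 91). Both sides of
the boundary are unit-tested. Era ends use a running maximum so overlapping
dispensings cannot shorten an era.

**New users.** A person enters the cohort at the start of their first era of
whichever study drug came first, provided they are ≥ 18 years old at index,
carry the indication code on or before index, and have ≥ 365 observed days
before index. Same-day initiation of both drugs is ambiguous and excluded.
Persons exposed to the other study drug before their index are excluded
entirely rather than censored — the cleanest new-user contrast; the
alternative (censoring at switch) changes on-treatment person-time but not
the design.

**Time at risk.** Follow-up always starts the day after index, so index-day
events never count (those persons remain in the cohort). The
intention-to-treat window ends at the first of: first event, end of
observation, index + 30 days. The on-treatment window replaces the fixed cap
with the index drug era's end plus a 14-day washout. Intervals are closed
integer-day ranges; person-time is kept in days and converted to years only
for reporting (365.25 days/year).

**Combination cohorts.** "Drug A plus drug B" exposure is expressed as a
derived code: the combination index is the second drug's first-era start if
it falls 0–30 days after the first drug's start while that era is still
ongoing. The 0–30-day window is a documented assumption (the source designs
do not state one in their main text); it is a `derive_combination_exposure()`
argument.

## Propensity model, stratification and balance

Treatment choice is modelled by L1-penalized logistic regression on all
baseline covariates (every condition code observed on or before index, plus
age and sex). The penalty is chosen by 10-fold cross-validation on
out-of-fold binomial deviance over glmnet's data-driven 20-point logarithmic
path; fold assignment is seeded so the fit is reproducible. Deviance rather
than AUC is used as the CV objective: the score enters downstream analysis
as a probability, and likelihood is the proper scoring rule for it (the
alternative was genuinely open; this is the package's choice).

Scores are cut at their pooled 20/40/60/80 percentiles into quintiles. Ties
are resolved by the right-closed interval they fall in; fully degenerate
scores collapse to a single stratum with a warning rather than an error, so
an unadjusted analysis is still produced and visibly flagged.

Balance is measured by the standardized mean difference,
`SMD = (mean_t − mean_c) / sqrt((var_t + var_c)/2)`, with *population*
variances so that binary covariates reproduce the textbook closed form
exactly. The post-stratification SMD pools within-stratum arm differences
with weights proportional to total stratum size (both arms combined) over
the crude pooled standard deviation. Any |SMD| > 0.1 after stratification
fails the balance gate and excludes the database's study estimates from
downstream synthesis; negative-control estimates are still computed, because
they are the diagnostic that would explain the failure. With the simulator's
default (deliberately strong, baseline-table-like) confounding, quintile
stratification can leave the strongest binary confounders just above the 0.1
line — the gate firing on such data is correct behaviour, not a defect; the
recovery experiments therefore report the ungated estimate alongside.

An equipoise summary on the preference-score scale is reported for
eyeballing only; nothing gates on it.

## Outcome model

Hazard ratios come from a Cox model conditioned on the propensity strata:
separate baseline hazard per stratum, the treatment indicator as the only
covariate, Efron's approximation for the ties that integer-day data
guarantee, Wald intervals. Analyses with zero events in *either* arm are
returned as exclusion records — a hazard ratio is simply inestimable then —
as are separated or non-convergent fits. (Whether the zero-event exclusion
should require both arms empty was open; either-arm-zero is implemented
because the estimate does not exist either way.) Incidence rates are
events per 1000 person-years; the minimum detectable relative risk uses the
standard two-sided normal approximation with person-time-proportional event
splits and is checked against a brute-force power simulation in the tests.

## Empirical calibration

Negative-control outcomes — believed causally unrelated to either drug —
should estimate HR 1; their spread reveals residual systematic error. The
package fits `log HR_i ~ Normal(mu, tau² + se_i²)` by maximum likelihood,
with `tau` parameterized as `log tau` plus an explicit check of the
`tau = 0` boundary (where `mu` has the closed-form precision-weighted-mean
solution). Systematic error is assumed independent of true effect size —
the simplest model consistent with negative-control calibration; positive
controls, which would let the error scale with the effect, are out of
scope. Calibrated p-values are two-sided tail probabilities of the observed
estimate under the fitted null; calibrated intervals shift the point
estimate by `−mu` and widen the half-width to `1.96·sqrt(tau² + se²)`. With
`mu = 0, tau = 0` every calibrated quantity equals its uncalibrated
counterpart, which the tests assert exactly. Zero-event controls are
dropped before fitting (no estimate exists), and fewer than five usable
controls skips calibration with a warning instead of fitting a meaningless
null. Calibration is applied per database before pooling; the alternative
(pool, then calibrate the summary) was open, and per-database-then-pool
matches calibrated per-source estimates feeding forest plots.

## Self-controlled case series

The SCCS compares event rates within a person between exposed and unexposed
time, eliminating every time-invariant confounder. Observation time is cut
at exposure-era boundaries (the 90-day-gap eras), calendar-quarter
boundaries, 5-year age-band birthdays and co-drug era boundaries; each
interval carries constant covariates and the count of events falling in it.
Conditioning on each case's total event count turns the per-person
likelihood into a multinomial over that person's intervals with
probabilities proportional to `length × exp(xβ)` — any per-person
multiplicative frailty cancels exactly, which the tests verify
algebraically. The exposure risk window is the era itself (no pre- or
post-exposure sub-windows); age bands of 5 years and seasons as calendar
quarters are configurable defaults, since only the covariates themselves,
not their granularity, are standard.

The exposure coefficient is never penalized; age/season/co-drug nuisance
coefficients are L1-regularized, with the penalty chosen by seeded k-fold
cross-validation over *cases* on out-of-fold conditional log-likelihood,
followed by an unpenalized refit on the selected support from which the
reported standard error comes (a relaxed-LASSO-style interval; the
post-selection caveat applies and is accepted). Optimization is Newton with
step-halving for the smooth fits (score tolerance 1e-10) and FISTA with
backtracking for the penalized ones. Cases with no exposed (or no
unexposed) time make the IRR inestimable and are flagged rather than
fitted. The event-dependent-observation correction (for outcomes that end
observation, like death) is deliberately not implemented; results tables
carry a placeholder column where those adjusted estimates would sit.

Calendar arithmetic uses day 0 = 1 January 2010 for every person, 365-day
years with 91/91/92/91-day quarters, and 365.25-day years for ages; leap
days are ignored at claims-day granularity.

## Evidence synthesis, gating and masking

Per-database estimates are pooled by DerSimonian–Laird random effects: the
between-database variance comes from comparing each database's estimate with
the inverse-variance fixed-effects mean (Cochran's Q), `tau² = max(0,
(Q − df)/(Σw − Σw²/Σw))`, weights `1/(se² + tau²)`. `I² = max(0, (Q −
df)/Q)`; when I² ≥ 0.4 the pair is *gated*: no pooled estimate exists,
`random_effects_pool()` refuses the input, and forest exports contain no
pooled row. The gate is applied to calibrated estimates (the quantities
actually pooled in per-source forest plots); whether the original studies
gated on calibrated or uncalibrated values is not stated, and this choice is
flagged as an assumption. Databases are treated as independent; a
`variance_inflation` argument (default 1) lets users acknowledge patient
overlap between sources, which otherwise underestimates the pooled
variance.

Count and rate pooling reproduces meta-analysis table rows: totals are
sums, pooled rates are total events over total person-time, and person-time
is back-derived as `events/rate` when only counts and rates are available.
Counts of 1–4 render exactly as `"<5"` (zero stays `"0"`; zero-event
analyses are excluded upstream anyway), and any rate computed from a masked
count renders as the `"<"` bound obtained from the threshold over the same
person-time, so masked cells propagate masked.

## The simulator: what it emulates, and what it does not

`sim_config()`/`simulate_claims()` generate persons with binary baseline
covariates (written as condition occurrences before index), one observation
period each, logistic confounded treatment assignment, era-fragmented
exposure records, and first-event outcome days drawn from exponential
hazards `λ·exp(covariate effects + arm effect)` measured from index, with
events after observation end censored. Negative controls share a baseline
hazard, have arm effect exactly 0, and can be given a common *unmeasured*
confounder channel (a latent binary U affecting both treatment choice and
control hazards) to inject calibratable systematic error. Random streams
are split per stage, so adding outcomes never perturbs the population or
the treatment assignment — a property the tests pin down. A separate
recurrent-event generator (`simulate_sccs_data()`) produces
piecewise-constant Poisson processes with per-person frailty for the SCCS.

Defaults are chosen once to resemble a rheumatoid-arthritis new-user
population: 78% female; lupus, psoriasis, Crohn's disease and heart disease
moving treatment choice in the directions seen in published baseline
tables (odds ratios near 3 in either direction for the strongest); 30-day
supplies with up to six refills and gaps ≤ 20 days; 200–1825 days of
pre-index observation. Baseline hazards and confounder effect sizes are
free parameters of the simulation — the source studies do not report
per-database values — and the chosen defaults (1e-3/day for a common
adverse event, 2e-4/day for negative controls) are documented config
values, not calibrated quantities.

What the simulator does **not** emulate: multiple observation periods per
person, coding-system vocabularies and database dialects, time-varying
hazards or seasonality in outcome risk, outcome-dependent censoring (so the
missing SCCS correction is untestable by design), exposure misclassification
and adherence gaps beyond the refill-gap distribution, and correlated
covariates beyond what the shared treatment/outcome effects induce. Passing
recovery tests therefore show the estimators are correct under the stated
generating model — not that any real database is free of the biases the
generator omits.

## Experiment sizes and numerical choices

The recovery experiments run at the sizes the package documents as its
study conditions: 50 replicates of n = 20 000 confounded cohorts (true
HR 2) through the full LASSO-PS → quintile → stratified-Cox chain, and 20
replicates of ~500-case SCCS data (true IRR 2); both recover the true log
effect to within 0.05 in mean. Calibration experiments use 40 controls per
replicate with injected bias mu = 0.25 for type-I restoration, and 100
controls with sampling SEs drawn U(0.03, 0.08) for null-parameter recovery —
the SE range is part of the experimental design: with much noisier controls
tau is not identifiable at that sample size and its MLE correctly collapses
to the boundary. Wald quantile 1.959964 throughout; Cox convergence at
coxph's defaults tightened to eps 1e-9; empirical-null optimization by
L-BFGS-B on `(mu, log tau)` with a tau = 0 boundary comparison; SCCS CV
folds capped at the number of cases.

## Known limitations

Only stratification is implemented (no matching or weighting); covariate
construction is the flat all-binary-indicators set, not hierarchical code
roll-ups; the calibration model is location–scale only (no effect-size
scaling, no positive controls); the SCCS has no event-dependent observation
correction and no spline age model; pooled analyses assume independent
databases unless the variance-inflation factor is used; and calibrated and
uncalibrated intervals are both Wald-type, so very sparse outcomes (a
handful of events) are better served by the exclusion rules than by the
estimates.
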