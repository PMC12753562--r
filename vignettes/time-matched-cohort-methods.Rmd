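---
title: "Time-matched new-user cohort studies from claims data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-matched new-user cohort studies from claims data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Claims databases record diagnoses, prescriptions, hospitalizations and a
thin stream of measurements for large populations, which makes them
attractive for post-marketing drug-safety questions — here, whether new
users of a triglyceride-lowering fibrate face an increased hazard of venous
thromboembolism (VTE) relative to dyslipidemia patients not treated with
any fibrate. Two well-known traps dominate this design:

* **Immortal time bias.** Exposed follow-up naturally starts at the first
  prescription, but an untreated comparator followed from diagnosis has
  been given extra, earlier person-time. Worse, anyone who must survive
  from diagnosis to treatment start to count as "treated" is immortal over
  that interval. `tmcohort` addresses this with *time-matching*: for an
  exposed patient whose first prescription came X days after their first
  dyslipidemia diagnosis, each candidate control's index date is placed X
  days after the candidate's own first diagnosis, so both clocks start the
  same design-time distance from diagnosis.
* **Confounding by indication.** Who gets the drug depends on baseline
  covariates that also predict VTE. The pipeline estimates a propensity
  score per patient and weights controls by the propensity odds
  `e/(1-e)` with exposed weight 1 (standardized mortality ratio weighting,
  SMRW), targeting the average effect in the treated (ATT).

The package implements the full pipeline — synthetic claims generation,
cohort construction, covariate extraction, multiple imputation, weighting,
and weighted survival analysis — as separable, individually tested stages
with plain CSV artifacts between them.

## The estimand and the analysis model

Follow-up runs from the index date to the first VTE event or censoring.
The hazard model is a weighted Cox proportional-hazards fit with the
exposure indicator as the *only* covariate; all covariate adjustment is
carried by the SMRW weights. Confidence intervals use the robust
(sandwich) variance, because weighting invalidates the model-based
information variance. Ties use the Breslow approximation by default (Efron
available). Two follow-up definitions are provided:

* **ITT** — exposure status frozen at index; follow-up ends at the event
  or the end of the patient's observable period, ignoring treatment
  changes.
* **PP (per-protocol)** — exposed members are additionally censored at the
  first prescription of a different fibrate or at the end of pemafibrate
  exposure; controls are censored when they start pemafibrate or another
  fibrate. Exposure episodes are built from refill records: each
  prescription covers `[date, date + days_supply - 1]`, consecutive
  supplies merge when the uncovered span is at most the *gap* period, and
  the final episode is extended by the *grace* period. The four scenarios
  use a shared gap/grace duration of 0, 30, 90 or 180 days.

With imputation, every estimate is computed once per completed dataset and
pooled by Rubin's rules: total variance `T = W + (1 + 1/m) B`, CIs from a
t reference with Barnard–Rubin degrees of freedom (classical Rubin df in
the infinite-complete-data limit).

## Outcome ascertainment

A VTE diagnosis code alone is not treated as an event (rule-out coding is
common in claims). An event requires a qualifying thrombolytic or
anticoagulant prescription: for outpatient records, for the same patient
at the same facility on the same date; for inpatient records, within the
same hospitalization, with the event date being the earliest qualifying
prescription on/after the diagnosis record. Two readings of "after the
record" are possible for inpatients; the package defaults to on-or-after
(a same-day prescription is exactly what the outpatient rule requires) and
exposes `rx_after_dx_strict` for the strict reading. If the only
qualifying prescription in a stay precedes the diagnosis record, the
co-occurrence condition is still met and that prescription date is used.

## Window conventions

Dates are day-granular integers; intervals are closed. The baseline window
for exclusions and covariates is `[index - 180, index - 1]`: the index day
itself belongs to follow-up, so the exposed member's own index-day
prescription does not trip the baseline fibrate exclusion. The control
pemafibrate lookback is `[index - 180, index]` *inclusive* of the index
day, since a control on pemafibrate at index would be exposed. The source
text specifies only "180 days prior to the index date"; this pair of
conventions is the internally consistent reading, and the inclusive
control bound is the conservative one. Age at index is completed years.
Person-years use 365.25 days per year.

A patient may appear in both groups (control early, exposed later at a
distinct index date), and a patient may serve as control in several
matched sets; within one matched set controls are sampled uniformly
without replacement. Matching processes exposed members in ascending index
date (ties by patient id) under one seed, so cohorts are exactly
reproducible. If a pool has fewer candidates than the matching ratio, the
whole pool is kept with a warning and the realized ratio is reported,
rather than dropping the exposed member.

## The synthetic claims generator

Real claims sources for this design are proprietary, so the package ships
a generator whose defaults emulate the study conditions and whose latent
state (the `truth` table) makes every downstream stage testable:

* Patient covariates follow the reported cohort structure: ~47% female,
  age ~N(66, 14) truncated to [20, 95], BMI ~N(24, 4.3), smoking 40%, and
  twelve code-defined covariates (diabetes 25%, cancer 20%, statin 25%,
  hypertension 14%, ... see `default_covariate_spec()`).
* Treatment initiation is a per-day hazard from the later of first
  diagnosis and drug launch, scaled by `exp(x'beta_treat)`. The default
  coefficients make initiators younger, more often male, heavier and more
  often diabetic — so the crude hazard ratio under a null effect is biased
  below 1, the direction reported for the real cohort.
* Outcomes are drawn as a piecewise-inhomogeneous Poisson process with
  rate `h0 * exp(x'beta_outcome)`, multiplied by `exp(true_log_hr)` while
  drug supply is active. Time to first event is therefore exactly
  piecewise-exponential, which gives the generator an exact
  inverse-transform sampling oracle (tested by a Kolmogorov–Smirnov
  distance). `h0` defaults to 3.6e-5 per day, about 1.3 events per 100
  person-years at reference covariates.
* Initiation is suppressed when an event precedes the latent initiation
  day: a patient who just had a VTE does not become a new fibrate user.
  This is precisely the mechanism that makes a naive ever-user/never-user
  comparison (implemented only in the test suite) exhibit immortal-time
  bias, while the time-matched design stays centred on the truth.
* Every event emits a diagnosis plus a same-day/same-facility (outpatient)
  or same-hospitalization (inpatient) qualifying prescription; a small
  fraction of patients receive a lone VTE diagnosis with no treatment,
  which the ascertainment algorithm must ignore. `inpatient_fraction`
  (default 0.2) applies to event records; routine covariate records are
  emitted as outpatient claims at ~90-day spacing so chronic conditions
  are visible in any 180-day baseline window.
* Refills draw supplies from {30, 60, 90} days with per-refill
  discontinuation probability 0.15 and a gap mixture (short gaps up to 14
  days; 20% long gaps of 20–120 days), so continuous, interrupted and
  discontinued exposure histories all occur and every gap/grace branch is
  exercised. Real refill patterns for this drug are not published;
  these defaults are stated, not calibrated.
* BMI and smoking measurements are deleted at a target rate of 80% under
  a MAR mechanism conditioned only on fully observed covariates (age,
  sex, diabetes), with the intercept calibrated by root-finding so the
  realized probability averages the target. At the cohort level the
  missing fraction is higher still (~90%), because measurements taken at
  diagnosis fall outside the 180-day baseline window whenever the X
  offset exceeds 180 days — similar in spirit to the real cohort, where
  BMI was known for only ~17% of members.

What the generator does **not** emulate: real coding dialects and fee
schedules, death as a competing risk, dose titration, facility-switching
care patterns, or measurement error in diagnoses. Passing tests therefore
demonstrate that the *pipeline* is correct under a known generative model,
not that any particular real-world estimate is right.

## Multiple imputation

Missing BMI category (six ordinal levels) and smoking are imputed by
fully conditional specification: smoking by Bayesian logistic regression
(posterior draw of the coefficients from the asymptotic normal, then a
Bernoulli draw), BMI category by a proportional-odds model with the same
draw-then-sample scheme. Predictors are all other covariates, the event
indicator, and log follow-up time (log scale is the standard choice for
survival-compatible imputation; the source is silent). Zero-variance
predictors are dropped and recorded, mirroring the published handling of a
covariate with no cases. Defaults: m = 20 imputations, 10 FCS sweeps
(sweep count is our choice; with only two imputed variables the chain
mixes almost immediately), initialization by draws from observed margins.
Component models that fail outright fall back to a small ridge penalty
with a warning. Observed cells are never altered — an invariant asserted
in the tests.

## Numerical choices and degenerate inputs

* Propensity models are main-effects logistic; BMI enters as integer
  scores of its ordinal category, consistent with its imputation model.
  Separation or non-convergence triggers a ridge-penalized refit
  (lambda = 1e-4) with a warning; fitted scores are clamped away from 0/1
  by 1e-8. No weight truncation by default; percentile truncation is
  available for extreme scores.
* Standardized differences use the pooled-variance formulas (binomial
  variance for 0/1 covariates, reliability-weighted variances otherwise),
  signed control-minus-exposed; balance assessments read the absolute
  value. A constant covariate with equal means gives 0; zero pooled
  variance with unequal means is an error.
* Zero-length follow-up (an event on the index day) is shifted to half a
  day so the Cox risk set is well defined. Monotone likelihood (all
  events in one group) yields a ridge-stabilized estimate with a warning;
  no events at all is an error.
* Episode merging treats `uncovered = next_start - current_end - 1 <=
  gap` as continuous, so gap 0 means seamless refills merge and any
  uncovered day splits — a strict inequality at 0 would forbid
  back-to-back refills.
* Subgroup analyses reuse the full-cohort weights (per-subgroup
  refitting is not described in the source design); levels with no events
  are flagged inestimable rather than dropped.
* Stage seeds derive from one master seed by fixed offsets
  (`seed * 101 + offset mod 2^31`), so a whole run is reproducible from a
  single integer and any stage can be re-entered.

## Problem sizes used in validation

The test suite validates the statistical properties at sizes chosen for
tight Monte-Carlo error at desk scale: covariate balance on a confounded
cohort generated from 20,000 patients with the full imputation pipeline;
null-coverage of the SMRW-weighted CI against the crude CI over 100
replicates of 8,000 patients; recovery of a true log hazard ratio of
log 2 over 60 replicates of 8,000 patients with persistent refills (so
exposure spans follow-up) under the PP-0 analysis. The recovery scenario
uses moderated outcome heterogeneity: hazard ratios are non-collapsible,
so under strong baseline-hazard heterogeneity the marginal ATT hazard
ratio sits measurably below the conditional one even for a perfect
estimator; moderating heterogeneity keeps the two estimands aligned so
the check isolates estimator bias (immortal time, weighting, episode
algebra) rather than collapsibility. The full-size end-to-end demo
(`run_study()` at n = 5,000, m = 20) completes in a few minutes on one
CPU.

## Known limitations

* The marginal/conditional distinction above applies to any real use:
  the reported HR is a population-averaged ATT hazard ratio.
* Control censoring at treatment start in the PP analysis is assumed
  independent of outcome given baseline covariates; time-varying
  confounding of initiation is out of scope.
* Death is not modeled as a competing risk; the observable period simply
  ends.
* The code dictionary shipped with the package matches the synthetic
  vocabulary; real-data users must supply their own prefix lists
  (`read_code_dictionary()`).
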