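---
title: "Estimating risks under sustained hypothetical interventions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating risks under sustained hypothetical interventions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfemula)
```

# The scientific problem

Long-running randomized trials of population-wide blood-pressure control or
smoking cessation in generally healthy older adults are infeasible, yet
decisions about such sustained strategies must be made. Target trial
emulation answers this with observational data: specify the protocol of the
hypothetical trial (eligibility, strategies, outcomes, follow-up) and mimic
each element analytically. Because the strategies are sustained over years
and the confounders they act through (SBP itself, medication use, incident
comorbidities) are themselves affected by earlier treatment, conventional
regression adjustment fails; a g-method is required. `gfemula` implements the
parametric g-formula — standardization generalized to time-varying exposures
and confounders — with death handled as a competing event.

The estimand is the cumulative incidence ("risk") of a first event over
`K_max + 1` discrete intervals of follow-up under full adherence to a
strategy, together with risk ratios and risk differences against the
*natural course*, the no-intervention simulation in which covariates evolve
according to their fitted models.

# The estimator

Follow-up is discretized into intervals `k = 0, ..., K_max` of roughly one
year; interval 0 is the baseline examination. The estimator proceeds in the
classical steps:

1. **Covariate models.** For each time-varying covariate, in a configured
   simulation order, fit a parametric regression on baseline covariates and
   covariate history among persons still under follow-up. Covariates are
   measured only at examination visits, so each model conditions on having
   attended the visit; the attendance indicator (the *visit process*) is
   itself the first modeled covariate. Between visits values carry forward.
2. **Hazard models.** Fit pooled logistic regressions for the event and for
   death over all at-risk person-intervals, approximating the discrete-time
   hazards.
3. **Pseudo-population.** Sample `n_sim` baseline records (default 10,000)
   with replacement from the eligible cohort.
4. **Simulation.** For each pseudo-individual and interval: draw the visit
   indicator; if attending, draw each covariate in order from its fitted
   model (each conditional on already-drawn current values and on history);
   apply the strategy's assignments; evaluate the event and death hazards on
   the intervened state.
5. **Risk.** Accumulate each history's cumulative incidence analytically
   from its hazard sequence and average over the pseudo-population.
6. **Contrasts.** Report each strategy against the natural course as a risk
   ratio and a risk difference, with percentile bootstrap confidence
   intervals (resampling persons with all their intervals; 500 replicates by
   default).

## Within-interval ordering

One fixed ordering is used everywhere — in the synthetic data generator, in
the risk-set definitions of the fitted models, in the simulator, and in the
oracle — so that estimator and truth are commensurable. Within interval `k`:
the visit/covariate update happens first, then the strategy assignment, then
death, then the event, then censoring. Consequently:

* hazards at `k` are functions of the (intervened) covariate state at `k`;
* the competing-risk cumulative incidence factorizes with death first,
  `risk(K) = sum_k h_e(k)(1 - h_d(k)) prod_{s<k}(1 - h_e(s))(1 - h_d(s))`;
* the event model is fit among at-risk records without a death that
  interval, and the death model among all at-risk records;
* a person who has an event at the interval of a protocol-censoring cutoff
  counts as an event (exits precede censoring within an interval).

## Competing events

Three modes are supported. `competing` (the default) estimates the total
effect on the event's cumulative incidence, letting interventions act also
through death. `censor_death` treats death as censoring, emulating a
counterfactual in which death is eliminated; it is reported for comparison
but rests on stronger assumptions, and for identical hazards it can only
raise the risk (a tested invariant). `composite` analyzes the combined
endpoint (event or death) with a single pooled logistic model.

## Analytic risks rather than exit draws

Step 5 computes each pseudo-individual's risk analytically from its hazard
sequence instead of drawing binary exits. This removes one layer of Monte
Carlo noise at no cost in bias: covariate transitions given history do not
depend on later exits, so the average of per-history cumulative incidences
equals the g-formula sum. The same analytic accumulation is used by the
oracle (below), and its agreement with exact enumeration on a saturated toy
model is part of the test suite.

# Strategies

Ten built-in strategies mirror a blood-pressure/smoking target trial:
natural course (0); maintain SBP below 120 (1) or 140 mmHg (2); reduce SBP
by 10% (3) or 20% (4) when above 140 mmHg; quit smoking (5); and the four
joint SBP + cessation strategies (6-9). Design choices where the protocol
label leaves freedom:

* **Set-to-threshold.** "Maintain SBP below T" assigns exactly `T` when the
  simulated value exceeds `T` — the minimal intervention consistent with the
  label, and the one that makes the intervened-percentage bookkeeping
  coherent.
* **Cessation maps current to former**, never to never: quitting cannot
  erase smoking history. Never- and former smokers are untouched.
* **Proportional reductions act once per interval** on the current
  simulated (pre-intervention) SBP. A value still above 140 after a 10%
  reduction stays where the reduction put it — that is precisely how
  strategy 3 differs from the threshold strategy 2. Assignment-based rules
  are idempotent; proportional rules are deliberately not.
* **Percent intervened** counts only actual changes: the cumulative share of
  pseudo-individuals whose state a strategy has altered at least once by
  interval `k`. The natural course is identically zero; a tighter threshold
  can only intervene on more people (a tested invariant).

# The synthetic cohort generator

The package ships a fully known data-generating process, `default_dgp()`,
emulating a population-based cohort of adults aged 55-80 followed over 16
yearly intervals with four examination rounds (intervals 0, 3, 7, 12):

* **Baseline.** Age uniform on [55, 80]; 57.3% women; baseline SBP normal
  (mean 137.3, SD 21.5 mmHg); smoking never/former/current at
  31.5/44.5/24.1%; education 48.6/41.8/9.6% (primary/further/higher);
  APOE-e4 noncarrier/carrier/missing at 68.7/26.8/4.5%; diabetes 12.9%,
  heart disease 7.7%, antihypertensive medication 27.6% (more likely at
  higher SBP); BMI, total cholesterol and alcohol at realistic scales
  (26.3 kg/m2, 6.7 mmol/L, 10.7 g/day).
* **Dynamics.** Thirteen time-varying covariates: the visit process
  (attendance about 85%, declining slightly with age and time), smoking with
  structural zeros (initiation is rare, relapse uncommon, quitting about 14%
  per visit and more likely after incident heart disease), autoregressive
  SBP (rising with age and time, lowered by medication), cholesterol, BMI
  and alcohol, medication uptake driven by current SBP, and six absorbing
  incident conditions (heart disease, diabetes, cancer, TIA, parkinsonism,
  and the other outcome acting as a time-varying confounder).
* **Hazards.** Logistic discrete-time event and death hazards in age, sex,
  current SBP, smoking, medication, incident comorbidities and time. The
  intercepts were calibrated once, by direct simulation from the process, so
  the natural-course 15-year event risk is about 10% and the death risk
  about 25% — the scale of a population-based stroke cohort. Effects flow
  through the intended channels: SBP raises both hazards, smoking raises
  both.
* **Incomplete data.** A small fraction of persons (2% SBP, 3% BMI) has the
  measurement missing until their first attended follow-up visit, emulating
  item missingness removed by complete-case eligibility filtering; about
  1% fails the MMSE criterion. Loss to follow-up adds a 0.4%-per-interval
  exit, independent of future covariates, on top of protocol censoring at
  missed visits.

A reduced process, `small_dgp()` (visit + SBP + medication, 8 intervals),
has the same qualitative structure and serves designs that refit the entire
pipeline hundreds of times, such as bootstrap coverage studies; problem
sizes for all shipped analyses are n = 5,000 persons for the main cohort and
n = 1,000 for nested-simulation replicates.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: unmeasured confounding (the simulated hazards
depend only on modeled covariates, so conditional exchangeability holds by
construction), measurement error in self-reported covariates, informative
loss to follow-up (available as an explicit stress-test option only),
calendar-time or geographic structure, and zero-inflation in alcohol intake
(modeled as truncated linear).

## Oracle counterfactual risks

`oracle_counterfactual_risk()` computes the ground truth for any strategy by
simulating directly from the true process with the strategy substituted into
the state before hazards are evaluated, with no loss to follow-up (incomplete
follow-up is an exit process, not part of the counterfactual estimand), but
with the visit process retained — covariates still update only at attended
visits. Risks are accumulated analytically per history (default 200,000
histories), so the Monte Carlo standard error is small and reported. The
test suite requires the estimator to recover these oracles within combined
standard errors for all ten strategies, on top of exact-enumeration checks
at toy scale.

# Numerical and statistical choices

* **Time terms.** All models include a linear-plus-quadratic interval index
  by default. Per-interval indicators are expressible through the term
  grammar but are separation-prone in hazard models at moderate cohort
  sizes, so they are not the default.
* **Default predictor sets.** Each covariate model uses all baseline
  confounder terms (quadratic age, sex, education, APOE-e4, baseline
  diabetes and heart disease, cubic baseline SBP), the time terms, lag-1
  values of every time-varying covariate, and current-interval values of
  covariates earlier in the simulation order. Hazard models use the baseline
  terms, time terms, and all current covariate values. The exact lag depth
  and interactions are configurable per covariate.
* **Smoking as stratified logits.** With never-to-former and back-to-never
  transitions structurally impossible, each origin state has exactly two
  reachable destinations; the multinomial with structural zeros therefore
  reduces to origin-stratified binary logistic models (initiation, relapse,
  cessation). These rare-transition models default to a parsimonious term
  set (age, sex, time, lagged heart disease).
* **Truncation.** Simulated continuous draws are truncated at the observed
  sample range of the covariate (standard practice to prevent extrapolation
  blow-ups); the residual SD of each linear model supplies the draw scale.
* **Degenerate fits.** A covariate constant in the fitting data is flagged
  and carried as a constant during simulation; aliased (rank-deficient)
  columns are dropped by zeroing their coefficients.
* **Bootstrap.** Percentile intervals from the 2.5/97.5 empirical quantiles
  with the inverse-ECDF convention (with B = 2, the bounds are the min and
  max). Point estimates come from the original sample. Replicate seeds
  derive deterministically from the master seed and replicate index, so
  replicates are order-independent and parallelizable; failed replicates
  (e.g. no events after resampling) are excluded and counted.
* **Common random numbers.** Within a run, every strategy is simulated from
  the same seed, so strategy contrasts are not inflated by independent Monte
  Carlo noise.
* **Protocol censoring.** A person who misses a scheduled visit is censored
  at that visit's window-end interval (default: scheduled interval + 1,
  configurable), implementing censoring at the last interval at which the
  missed examination could have taken place.
* **Subgroups are refit.** Each subgroup analysis refits every model within
  the subgroup rather than restricting the pseudo-population of the
  full-cohort fit, because subgroup-specific natural-course risks are part
  of the report. Six definitions are built in (age 55-65, 66-80, women, men,
  no baseline antihypertensive medication, free of baseline heart disease).
* **Interval convention.** `K_max = 15` yields 16 intervals approximating
  15 years; the interval length is configurable because nothing in the
  estimator ties it to calendar years.

# Diagnostics

`natural_course_diagnostics()` implements the standard calibration check:
for every time-varying covariate and visit interval, the observed mean among
at-risk visit attendees is compared with the natural-course simulated mean,
weighted by each pseudo-individual's analytic probability of still being at
risk and restricted to simulated attendees. Differences are reported raw and
standardized by the observed SD. The observed nonparametric cumulative
incidence (a discrete-time Aalen-Johansen analogue with death first) is
compared against the simulated natural-course risk. Under correct
specification on the synthetic cohort the maximum absolute standardized
difference stays below 0.1, and deliberately omitting the SBP lag makes the
SBP rows drift — both are acceptance-tested. `reorder_sensitivity()` reruns
the pipeline under permutations of the covariate simulation order as a
further misspecification probe.

# Worked example

```{r example, eval = FALSE}
dgp <- default_dgp()
config <- config_for_dgp(dgp, n_sim = 10000, seed = 1)

cohort <- generate_cohort(dgp, 5000, seed = 1)
cohort <- apply_eligibility(cohort)
cohort <- censor_at_missed_visit(cohort, config)

result <- run_strategies(cohort, config)
print(result)

diag <- natural_course_diagnostics(cohort, config)
print(diag)

# percentile bootstrap CIs (500 replicates by default; heavy)
effects <- bootstrap_cis(cohort, config, B = 100)
print(effects)
```

# Known limitations

The parametric g-formula inherits the g-null paradox: with misspecified
models, the natural course and a truly null strategy can diverge. The
diagnostics above probe but cannot prove correct specification. Strategies
assign SBP values without modeling *how* the reduction is achieved, so
estimates bundle all means of lowering SBP. Alcohol's point mass at zero is
not modeled. Multiple-imputation of missing covariates and continuous-time
observation schemes are out of scope; eligibility filtering is
complete-case at baseline with missing APOE-e4 retained as its own category.
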