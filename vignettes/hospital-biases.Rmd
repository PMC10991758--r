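---
title: "Competing risks, immortal time and confounding in hospital cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing risks, immortal time and confounding in hospital cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccwsim)
```

## Scope

`ccwsim` packages, as tested and reusable code, a complete demonstration of
how three methodological biases — competing risks, immortal-time bias, and
baseline confounding — distort treatment-effect estimates in observational
hospital cohorts, together with the analysis designs that remove them. Its
centrepiece is a clone-censor-weight target-trial emulation; around it sit
a calibrated synthetic-cohort generator, weighted nonparametric estimators,
a Fine-Gray subdistribution analysis, inverse-probability weighting,
multiple imputation, and a five-model comparison harness. This vignette
records the statistical model, every tunable that matters, the numerical
conventions, and the design decisions that were genuinely open.

## The cohort model

A patient is admitted on day 0 and followed on integer days `1..45`
(`admin_end`, configurable). Exactly one of four things ends follow-up:
in-hospital death, discharge home, transfer to another healthcare facility,
or administrative censoring at day 45. Death, home and transfer are
*competing events*: whichever comes first precludes the others. A
single-dose treatment may be initiated on any day before the terminal
event; its initiation is more likely for sicker patients (confounding by
indication) and its effect multiplies each cause-specific hazard from the
day *after* initiation.

### Baseline covariates

Each patient carries age (years), sex, Charlson comorbidity index, five
inflammatory markers — C-reactive protein (mg/L), lactate dehydrogenase
(U/L), D-dimer (ng/mL), total lymphocyte count (10^6/L), ferritin (mcg/L)
— and a pandemic-wave category (three levels). The markers and the
Charlson index share a standard-normal latent severity factor; given the
factor, covariates are independent. This creates realistic positive
correlation among the markers (and hence genuine multivariable
confounding) without committing to a full correlation matrix that no
public source pins down. Marker scales are anchored so that the high-risk
clinical thresholds (CRP > 102 mg/L, LDH > 394 U/L, D-dimer > 1,580 ng/mL,
lymphocytes < 760 x 10^6/L, ferritin > 1,360 mcg/L) fall in the outer
quantiles of each marginal distribution: for example CRP is log-normal
with median 60 mg/L and log-scale SD 0.9 including the severity loading,
putting 102 mg/L near its 72nd percentile.

### Hazards, treatment, and time conventions

On each day `t`, for a patient still in hospital, cause-specific hazard
*rates* are

    h_k(t) = exp(log_base_k + coef_k' z + treated(t) * log_hr_k),

where `z` is the internally standardised covariate vector and
`treated(t) = 1` iff the patient initiated on a day strictly before `t`.
The probability of any event on the day is `1 - exp(-sum_k h_k)`, and the
cause is drawn multinomially with probabilities proportional to `h_k`;
sampling "any event, then cause" avoids same-day ties between causes.
Because the `h_k` are rates, not probabilities, a value above 1 is legal
and simply drives the daily event probability toward 1; the no-event and
certain-event limits in the test suite exercise both extremes.

Treatment initiation is drawn *before* the event on the same day grid:
`P(initiate on day t) = plogis(a0 - decay (t - 1) + a' z)` for patients
not yet treated (optionally only up to `init$end_day`). The decaying
intercept reflects how such treatments are concentrated shortly after
admission. A patient can initiate and die on the same day; by the
effect-from-next-day convention that death is an untreated death, and the
counting-process view accordingly gives such patients a single untreated
interval. This convention prevents zero-length intervals and makes the
generator, the start-stop coding and the emulation mutually consistent; it
is a documented choice, not an inference about any particular registry.

### Calibration

The three baseline log-hazards and the two initiation parameters were
calibrated by iterative simulation (100,000 patients per iteration,
proportional log-scale updates) against six target margins typical of a
moderate-to-severe COVID-19 hospital population: 38.3% death, 49.6%
discharged, 12.3% administratively censored, 58.6% of discharges going
home, 29.9% ever treated, 15.3% treated within 2 days of admission. The
frozen defaults reproduce all six within half a percentage point on a
fresh 50,000-patient simulation; the acceptance script recomputes them at
any seed. All covariate effect sizes (e.g. +0.45 log-hazard per age SD for
death, -0.35 for discharge home) are design choices on scales a clinician
would find plausible; no public table constrains them, so they are stated
here once and not tuned further.

### Missingness

Only the five inflammatory markers can be missing. MCAR masks each value
independently; MAR (the default, rates 5-15% per marker) makes the masking
probability a logistic function of age and wave — fully observed
covariates — with the intercept solved per marker so the realised rate
matches the configured one on the cohort at hand. MAR-on-observables keeps
multiple imputation nontrivial but recoverable.

## Nonparametric estimators

`kaplan_meier()` and `aalen_johansen()` are weighted product-limit
estimators accepting `(start, stop]` counting-process rows with
per-interval weights — the form the emulation produces, where a clone's
inverse-probability-of-censoring weight changes day by day inside the
grace period. A subject is at risk at `t` iff `start < t <= stop`, so at a
tied day events precede censorings. The `cif_set` invariant
`sum_k CIF_k(t) + S(t) = 1` holds identically because the overall survival
is built from the pooled event counts. Both estimators are verified to
1e-12 against a brute-force day-by-day occupancy oracle, and against
`survival::survfit` as an independent cross-check; weighted estimates with
integer weights equal unweighted estimates on row-replicated data, and all
estimates are invariant to weight rescaling.

## Fine-Gray via censoring-weighted expansion

`finegray_expand()` keeps patients with a competing event in the target
cause's risk set to the end of follow-up, with time-varying weight
`G(t-)/G(T-)`, `G` the Kaplan-Meier estimate of the censoring
distribution, and intervals split at censoring times so the weights are
piecewise constant. Two discrete-time conventions were genuinely open and
were fixed by an analytic requirement: the unadjusted subdistribution CIF
must equal the Aalen-Johansen CIF computed under the same censoring
definition. That identity forces (i) the censoring risk set on a tied day
to exclude that day's events, and (ii) `G` to be estimated from *all*
causes classified as censoring in the chosen partition — in the two-event
analysis, transfers count as censoring for `G` too. With these conventions
the identity holds to machine precision on random datasets; under the
default design, where the only censoring is administrative at day 45, the
distinction vanishes. Weights below 1e-8 are floored to avoid numerical
blow-up in the degenerate case `G -> 0`.

The motivating three-way comparison — naive `1 - KM` vs the two-event vs
the three-event Fine-Gray CIF for death — is ordered
`naive >= FG(2) >= FG(3)` at the end of follow-up: each competing event
retained in the risk set removes probability mass wrongly attributed to
death.

## Cox engine

`fit_cox()` fits the weighted Cox partial likelihood on start-stop rows
through `survival::coxph`, with Efron ties by default: the daily grid
produces many tied event times, and Efron's approximation is less biased
there; Breslow is retained because the brute-force likelihood oracle in
the tests enumerates the Breslow likelihood exactly. Robust (sandwich)
variances group score residuals by `patient_id`, so the clones and
intervals of one patient form one cluster. Degenerate covariates raise an
explicit error; a monotone likelihood is flagged, the coefficient capped
at |15|, and a warning issued. The coefficient is verified to 1e-6 against
grid maximisation of the explicitly enumerated partial likelihood on small
datasets, and the engine's internal fitting routine (used unwrapped in the
bootstrap hot path for speed) is asserted to agree with the wrapped fit to
1e-10.

Lab covariates enter all regression models on transformed scales to tame
their right skew: log for CRP, LDH, D-dimer and ferritin; square root for
the lymphocyte count. The allocation of log vs square root is a package
decision — counts are conventionally square-rooted, concentrations
logged — fixed once in `baseline_covariates()` and used consistently by
the generator's confounding checks, the propensity model, the censoring
weights and Models 3-5.

## Weighting

The Model-4 propensity is the probability of *ever* receiving treatment
given baseline covariates (logistic regression); the weighted
time-dependent Cox model then uses these time-fixed weights with a
time-varying treatment status. Weights are stabilised by default (mean ~ 1)
and truncated at the 99th percentile; propensity scores are floored at
1e-6. Stabilisation and truncation levels are configurable because no
single convention is canonical.

The censoring weights for the emulation come from pooled daily logistic
models — one per arm, over days `1..grace`, with a day intercept and the
baseline covariates. A discrete-time model is the natural scale for a
2-day grace window; a Cox censoring model would buy nothing here. Days on
which an arm has no artificial censoring contribute probability exactly 1
(in the covariate-free case the pooled model is saturated and reduces to
the observed daily fractions). The clone weight at day `t` is the inverse
cumulative product of the fitted daily probabilities up to
`min(t, grace)`, constant afterwards, truncated at the 99th percentile. An
arm in which *every* clone deviates within the grace window is an error —
that emulation is undefined, not repairable.

Standardized mean differences use the pooled-variance form
`(m1 - m2)/sqrt((v1 + v2)/2)`, with weighted moments when weights are
supplied and proportion-based variance for binary covariates. Cloning
makes all baseline SMDs exactly zero by construction — the emulation's
built-in answer to baseline confounding — and IPTW on the default
confounded cohort brings the maximum absolute SMD from ~0.4 to below 0.1
at n = 5,000.

## The emulation

`clone_and_censor()` duplicates each patient into a treated-strategy arm
(initiate within the grace period, default 2 days, i.e.
`treatment_day <= 2` with admission = day 0) and a control-strategy arm
(do not initiate within the grace period). A clone is artificially
censored the day its source deviates: at the grace end for treated-arm
clones never treated in the window, at the initiation day for control-arm
clones treated inside the window. Events on or before the deviation day
take precedence, so patients with early events appear in both arms and no
immortal time is created. Initiation *after* the grace period is not a
control-arm deviation: the strategies constrain only the grace window. (A
never-treat control strategy is expressible by setting the generator's
initiation window instead.)

`emulate_trial()` chains cloning, censoring weights, per-arm weighted
Aalen-Johansen curves over the three endpoints, and one weighted
cause-specific Cox fit per endpoint with the arm indicator as sole
covariate and patient-clustered robust variance. `bootstrap_ci()`
resamples *patients* (never clones), reruns the whole pipeline per
replicate, and returns the normal-based interval
`exp(log HR +/- 1.96 SD_boot)`; replicate failures above 10% abort with a
diagnostic. The default 500 replications follow common practice; the
validation studies use 100 to keep runtimes reasonable.

### What the recovery study estimates, and why its design looks the way it does

Under a grace period the treated-arm clone spends the grace window partly
untreated (the effect starts the day after initiation), and early events
are shared by both arms; the arm contrast is therefore a per-protocol
effect *diluted during the grace window*, and only approaches the
configured conditional hazard ratio when the window's share of events is
negligible. A recovery study that compared the 2-day-grace estimand
against the configured log-HR would measure this estimand mismatch (about
+0.07 on the log scale at HR 0.7), not estimator error. The packaged
recovery design (`recovery_config()`) therefore randomises initiation to
day 1 only (probability 0.30), uses a 1-day grace, scales the baseline
hazards by 0.5 to shrink the day-1 event share, and removes covariate
effects from the outcome hazards so that the marginal arm contrast and the
conditional hazard ratio coincide (Cox hazard ratios are not collapsible
over heterogeneous baselines). Under that design the validation suite
recovers a true death log-HR of log 0.7 with absolute bias below 0.05 for
both the start-stop model and the emulation (200 replicates of n = 2,000),
and the bootstrap interval's empirical coverage sits in the low-to-mid
90s. Confounding adjustment is deliberately *not* part of this scenario —
it is validated separately through the balance contracts.

The immortal-time direction study uses the complementary scenario: null
treatment effects with delayed, covariate-independent initiation spread
over the whole stay. There the baseline-misclassified Model 1 averages a
death hazard ratio clearly below 1 while the start-stop Model 2 stays
centred on 1 (50 replicates of n = 5,000) — immortal time alone
manufactures apparent effectiveness.

## Multiple imputation

`impute_cohort()` is chained-equations imputation specialised to the
five-marker missingness pattern: each cycle redraws every incomplete
marker, on its analysis transform, from a Bayesian linear regression
(posterior draw of the residual variance and coefficients, then noise) on
the other baseline covariates, the other markers' current imputations, the
event-type indicators and the Nelson-Aalen cumulative all-cause hazard at
the event day. Including the outcome information guards against the
congeniality bias that arises when survival models are fit to data imputed
without it. Defaults are m = 5 copies and 5 cycles; a cohort with no
missing values yields m identical copies, which makes the zero-missingness
pipeline *bitwise* equal to the complete-data pipeline. `pool_rubin()`
combines per-copy estimates on the log-HR scale with
`T = W + (1 + 1/m) B` and Barnard-Rubin degrees of freedom (reducing to
the classic `(m - 1)/lambda^2` when the complete-data df is infinite).

## The five-model comparison

`run_five_models()` produces the 15-cell table (5 models x 3 endpoints)
with Yes/No flags for whether each model addresses immortal time and
baseline confounding: Model 1 (misclassified baseline treatment) suffers
both; Model 2 (univariable start-stop) only confounding; Models 3-5
neither. When markers are missing, the whole model set runs on each
imputed copy and is Rubin-pooled. The report also carries the
naive-per-group `1 - KM` versus emulated weighted-AJ day-45 death
probabilities, and exports to CSV, JSON and Markdown with seed, package
version and a cohort fingerprint for provenance. One root seed drives
generation, imputation and bootstrap so any stage can be re-run
independently yet reproducibly.

## Validation scale and limitations

The test suite's problem sizes are chosen to keep the full run in the
tens of minutes on one core while leaving Monte-Carlo error well inside
the asserted tolerances: 50,000 patients for calibration margins; 100
random datasets for the estimator oracles; 50 replicates of n = 5,000 for
the immortal-time direction; 200 replicates of n = 2,000 (100 bootstrap
replications each) for parameter recovery and coverage; n = 5,000 for the
balance and imputation contracts.

What the generator does *not* emulate bounds what passing tests show about
real data: covariates are time-fixed (no post-baseline confounding, which
the weighting models therefore cannot and do not adjust for);
hazards are time-constant given covariates; transfers are absorbing (no
readmission, no post-discharge mortality); follow-up is a hard 45-day
horizon; and the latent-severity correlation structure is a stylised stand-
in for unknown real-world dependence. The nonparametric curves carry no
variance estimates — interval estimation is delegated to the bootstrap on
the hazard-ratio scale. Within those bounds, the package's claims are
mechanical: every estimator is checked against an independent oracle, every
bias direction against a scenario in which the truth is known by
construction.
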