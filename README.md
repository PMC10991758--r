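# ccwsim

Competing risks, immortal-time bias and baseline confounding distort
treatment-effect estimates in observational hospital studies — and they do
so in different directions at once. `ccwsim` is an R package for
biostatisticians and epidemiologists who want to *demonstrate, quantify and
correct* these biases on realistic hospital data. It provides:

* a calibrated discrete-time simulator of COVID-19-like hospital cohorts
  with three competing endpoints (in-hospital death, discharge home,
  transfer to another facility), a confounded time-dependent single-dose
  treatment, and missing inflammatory markers;
* weighted nonparametric estimators (Kaplan-Meier, Aalen-Johansen) and a
  Fine-Gray subdistribution-hazard analysis built on a
  censoring-distribution-weighted data expansion;
* five treatment-effect models of increasing rigour, from a deliberately
  immortal-time-biased Cox model to a clone-censor-weight target-trial
  emulation with inverse-probability-of-censoring weights and bootstrap
  confidence intervals;
* chained-equations multiple imputation of the inflammatory markers with
  Rubin pooling.

## The statistical core

**Competing risks.** With cause-specific hazards `h_k(t)` for causes
`k = death, home, transfer`, the cumulative incidence of death is estimated
by the Aalen-Johansen estimator

    CIF_k(t) = sum_{t_j <= t} S(t_j-) d_kj / n_j ,

with `S` the all-cause Kaplan-Meier survival. Treating discharges as
censoring instead (the naive `1 - KM`) assumes discharged patients keep
dying at the in-hospital rate and therefore over-estimates `CIF_death`
everywhere. The Fine-Gray model regresses the *subdistribution* hazard:
patients with a competing event stay in the risk set, down-weighted by the
censoring distribution `G(t-)/G(T-)`.

**Immortal time.** A patient treated on day `t` cannot have died before
`t`; attributing the pre-treatment person-time to the treated group (Model
1) deflates the treated group's event rate and biases the hazard ratio for
death downward. Start-stop (counting-process) coding with a time-varying
treatment status (Models 2-4) removes the bias.

**Clone-censor-weight emulation (Model 5).** Every patient is cloned into
both arms of a hypothetical trial — initiate treatment within a 2-day grace
period vs. do not — and a clone is artificially censored the day its
source patient deviates from the arm's strategy. Cloning balances baseline
covariates exactly; inverse-probability-of-censoring weights (pooled daily
logistic models on baseline covariates) correct the selection induced by
artificial censoring; weighted Aalen-Johansen curves and weighted
cause-specific Cox models give per-arm cumulative incidences and hazard
ratios, with patient-level bootstrap confidence intervals.

## Worked example

```r
library(ccwsim)

cohort <- generate_cohort(default_config(), n = 3000, seed = 64)
run_motivating_example(cohort)
#> Cumulative in-hospital death probability at end of follow-up:
#>   naive 1-KM       59.5%
#>   Fine-Gray (2)    45.8%
#>   Fine-Gray (3)    39.1%
```

The naive estimator censors all discharges and overstates in-hospital
mortality; keeping discharge home in the risk set (Fine-Gray with 2
events) lowers it; keeping both discharge destinations (3 events) lowers
it further, to the fraction of patients actually observed to die.

```r
report <- run_five_models(cohort, trial_protocol(n_boot = 0, seed = 3))
report$table[report$table$endpoint == "death",
             c("model", "hr", "lower", "upper")]
#>  model        hr     lower     upper
#>      1 0.9281733 0.8211618 1.0491303
#>      2 1.1163274 0.9804403 1.2710482
#>      3 0.6561997 0.5713151 0.7536963
#>      4 0.7779151 0.6728221 0.8994232
#>      5 0.7642828 0.6571433 0.8888901
```

The simulator's true cause-specific death hazard ratio is 0.70, but
treatment goes preferentially to sicker patients. The univariable Model 2
is therefore confounded toward apparent harm (1.12); Model 1 additionally
misclassifies ever-treated patients as treated from admission, and the
immortal person-time drags its hazard ratio below Model 2 (0.93 < 1.12) —
the signature direction of immortal-time bias. Models 3-5 adjust for the
baseline covariates (by regression, by propensity weighting, and by
cloning plus censoring weights) and move back near the true 0.70.

```r
report$fig2$at_end
#>    naive_treated  naive_untreated emulated_treated emulated_control
#>        0.5907648        0.5966767        0.3235907        0.4063817
```

The per-group naive `1 - KM` death probabilities exceed the emulated
weighted Aalen-Johansen arm probabilities, and the naive contrast between
self-selected groups (0.59 vs 0.60) hides the treatment benefit that the
emulated arms reveal (0.32 vs 0.41): the naive analysis both ignores
competing discharge events and compares incomparable groups.

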