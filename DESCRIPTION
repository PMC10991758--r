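Package: ccwsim
Title: Competing Risks, Immortal-Time and Confounding Bias in Hospital
    Cohorts via Clone-Censor-Weight Target-Trial Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates COVID-19-like hospital cohorts with three competing
    endpoints (in-hospital death, discharge home, transfer to another
    facility), a confounded time-dependent single-dose treatment, and
    missing inflammatory markers, and analyses them with five
    treatment-effect models of increasing rigour: a deliberately
    immortal-time-biased Cox model with treatment misclassified at baseline,
    univariable and multivariable time-dependent Cox models in start-stop
    notation, an inverse-probability-of-treatment-weighted Cox model, and a
    clone-censor-weight target-trial emulation with inverse probability of
    censoring weights, weighted Aalen-Johansen cumulative incidence, and
    bootstrap confidence intervals.  Also provides weighted Kaplan-Meier and
    Aalen-Johansen estimators, Fine-Gray subdistribution-hazard analysis via
    censoring-distribution-weighted data expansion, standardized-difference
    balance diagnostics, and chained-equations multiple imputation of
    inflammatory markers with Rubin pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cmprsk
Config/testthat/edition: 3
RoxygenNote: 7.3.3
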