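Package: psorelapse
Title: Psoriasis Relapse Risk Score: Meta-Analytic Construction and
    External Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds an additive clinical point score for the risk of
    psoriasis relapse after discontinuation of biologic therapy, from
    meta-analytically pooled relative risks (heterogeneity-gated
    fixed/random-effects pooling, beta = ln RR, times-ten point weights,
    stratified scoring), and validates it on patient cohorts: ROC/AUC
    with DeLong confidence intervals, Youden-optimal cutoff, decision
    curve analysis, and Kaplan-Meier risk-group stratification with
    proportional-hazards contrasts. Includes a calibrated synthetic
    cohort generator emulating the validation population so the whole
    pipeline can be exercised without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    metafor,
    pROC,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
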