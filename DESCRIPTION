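Package: sgascreen
Title: First-Trimester Competing-Risks Screening for Small-for-Gestational-Age
    Neonates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Fetal Medicine Foundation style competing-risks model
    for first-trimester prediction of delivery of a small-for-gestational-age
    (SGA) neonate, together with the validation pipeline used in external
    validation studies: multiples-of-the-median (MoM) conversion of the uterine
    artery pulsatility index, PAPP-A and PlGF; a Bayesian posterior over the
    joint distribution of gestational age at delivery and birth-weight Z-score;
    risks for any (birth-weight percentile, gestational-age cut-off) pair;
    discrimination (AUC, detection rate at fixed false-positive rate),
    calibration (slope and intercept) and paired McNemar comparisons against
    published logistic-regression comparator models. A calibrated
    synthetic-cohort generator reproduces the outcome incidences and maternal
    marginals of a large multicenter screening population so that every
    pipeline stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
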