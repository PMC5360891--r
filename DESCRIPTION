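Package: copdwatch
Title: Identification and Prediction of COPD Exacerbations from Telemonitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chronic obstructive pulmonary disease (COPD)
    telemonitoring data. A three-state finite-state machine turns self-reported
    symptom-diary and medication data into per-patient state timelines and
    exacerbation events; labelled 7-day stable and prodromal windows are
    extracted with guard bands; respiratory rate is estimated from 30-second
    pulse-oximeter photoplethysmogram segments using heart-rate-adaptive
    low-pass filtering and the median of autoregressive spectra; per-window
    linear-trend features feed a logistic classifier evaluated with repeated
    10-fold cross-validation (mean ROC curve, confidence bands, AUC, and
    specificity at fixed sensitivity). A seeded synthetic-cohort generator
    emulates the statistical structure of a year-long telemonitoring trial for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
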