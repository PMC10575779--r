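Package: ironbio
Title: Case-Control Analysis of Postmortem Brain Iron Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for postmortem case-control studies of
    cortical trace-metal biology. Provides a synthetic-cohort generator that
    emulates multi-brain-bank case-control structure (age-dependent iron
    accumulation, variance heterogeneity, iron-coupled ferritin), cohort
    input/validation and demographic summaries, control-anchored z-score
    harmonization across banks, MM-estimator robust linear regression
    (IRWLS with Tukey bisquare loss), serial-cutoff logistic odds-ratio
    scans with influence-diagnostic exclusion, ROC analysis with
    bias-corrected bootstrap confidence intervals and combined risk-flag
    classification, and confounder-robustness tools (propensity-score
    matching, single-mediator analysis, medication-association tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    withr,
    yaml
Suggests:
    MASS,
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
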