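Package: adetrigger
Title: Trigger-Based Active Surveillance of Adverse Drug Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for active surveillance of adverse drug events (ADEs)
    in hospitalized patients using a configurable trigger rule set in the
    style of the Global Trigger Tool. Provides a relational cohort data model
    for hospitalization records (demographics, laboratory observations,
    medication exposures, clinical events, interventions), a rule engine that
    evaluates laboratory, antidote, symptom and intervention triggers against
    each admission, bookkeeping for dual-reviewer adjudication with WHO-UMC
    causality and NCC MERP severity grading, detection-performance metrics
    (positive predictive value, sensitivity, specificity, Youden index, ADE
    incidence rates), chi-square and logistic-regression risk-factor
    analysis, Delphi expert-consensus statistics for trigger item selection,
    and a synthetic cohort generator with a complete ground-truth ledger for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
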