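Package: mddscreen
Title: Structured DSM-5 Depression Interview Engine and Diagnostic Test Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Text-mode structured-interview engine for major depressive
    disorder (MDD) built on the DSM-5 criteria: a validated branching
    question bank, a deterministic dialog state machine, and a decisional
    algorithm tree that classifies completed transcripts. Companion
    modules score the Beck Depression Inventory II (BDI-II) and the
    Acceptability E-scale (AES), compute internal-consistency
    reliability (Cronbach's alpha), and evaluate diagnostic accuracy
    against a reference standard: confusion tables,
    sensitivity/specificity/predictive values with exact Clopper-Pearson
    confidence intervals, and single-operating-point ROC/AUC with
    Hanley-McNeil inference, overall and stratified by depression
    severity. A seeded synthetic patient-cohort simulator with
    configurable prevalence, severity mixture, severity-dependent
    detection and correlated questionnaire items makes the whole
    evaluation pipeline reproducible without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
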