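Package: mepprog
Title: Motor Evoked Potential Time-Series Features for Predicting
    Disability Progression in Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting two-year disability progression in
    multiple sclerosis from motor evoked potential (MEP) recordings.
    Implements recording-level preprocessing (duration and facilitation
    filters, dialect downsampling, maximum-amplitude selection, stimulus
    artifact trimming), the EDSS-based progression labelling rules, a
    catalog of time-series features with robust sigmoid normalization and
    left-right symmetrization, a feature-selection cascade (mutual
    information preselection, correlation-distance clustering, Boruta
    shadow-feature selection), per-anatomy random forest and logistic
    regression classifiers with visit-level prediction averaging, and a
    grouped stratified shuffle-split evaluation engine with paired DeLong
    AUC testing. A synthetic MEP cohort generator with known ground truth
    makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
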