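Package: lineupROC
Title: ROC, Confidence-Accuracy and Signal-Detection Analysis of Eyewitness Lineup Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneous eyewitness lineup identification
    experiments with target-present and target-absent lineups. Provides
    correct and estimated false identification rate estimators with
    chi-square comparisons, confidence-based ROC curves with partial AUC
    and bootstrap Z-tests, confidence-accuracy (CAC) and response-time-
    accuracy (RAC) characteristic curves with bootstrap confidence
    intervals, an equal-variance independent-observations signal-detection
    model for lineups (maximum-likelihood fitting, d-prime, model ROC
    curves), and a trial-level simulator supporting simulation-based power
    analysis for pAUC comparisons. Ships the frequency table of a large
    published verbal-overshadowing lineup study of young and older
    witnesses as a regression fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
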