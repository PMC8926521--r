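Package: afboost
Title: ECG Beat Classification and P-Wave Markers for Post-CABG Atrial
    Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting new-onset
    atrial fibrillation after coronary artery bypass grafting from the
    surface electrocardiogram. Provides a seeded sum-of-Gaussians 12-lead
    ECG generator with exact ground-truth fiducials, power-line notch and
    baseline-drift preprocessing, wavelet-based R-peak detection and
    P-wave delineation, the P-wave dispersion markers Pmax, Pmin and the
    P-terminal force in lead V1 (PTFV1), a from-scratch Gentle AdaBoost
    beat classifier with a back-propagation comparator and a train/test
    exchange benchmark, and a clinical statistics layer (cohort summaries,
    t and chi-square tests, binary logistic regression with Wald odds
    ratios, ROC curves with Youden-index cutoffs and diagnostic metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
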