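Package: fnirsbluff
Title: Simulation and Classification of fNIRS Lie-Detection Recordings from
    an Interactive Bluff Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for continuous-wave functional
    near-infrared spectroscopy (fNIRS) recordings acquired during an
    interactive bluff card game, in which subjects spontaneously lie or tell
    the truth while declaring their cards.  Simulates dual-wavelength raw
    intensity recordings with hemodynamic responses and physiological noise,
    converts intensities to oxy- and deoxy-hemoglobin concentration changes
    via the modified Beer-Lambert law, low-pass filters and epochs the
    claim windows, extracts signal-mean and signal-slope features, and
    classifies lie versus truth with three small multilayer perceptrons
    (trained from scratch with Kaiming-uniform initialization) alongside
    k-nearest-neighbour, decision-tree and polynomial-kernel support vector
    machine baselines.  Evaluation covers confusion matrices, ROC/AUC,
    stratified train/validation/test splits, leave-one-subject-out
    cross-validation and a per-subject sample test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
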