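Package: oastratify
Title: Knee Osteoarthritis Patient Stratification with SVM Classifiers and a
    Regulatory Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for stratifying knee osteoarthritis
    patients from clinical questionnaire descriptors, synovial fluid
    analyte panels, and simulated transcription factor activations.
    Ordinal clinical descriptors are binarized by a grid search
    maximizing Youden's index with a train-accuracy retention gate;
    per-patient transcription factor activities are obtained as steady
    states of a normalized-sigmoid regulatory network ODE model driven
    by rescaled synovial fluid analyte levels; nested leave-one-out
    linear support vector machine classifiers with inner 5-fold penalty
    tuning yield fold-averaged normalized feature importances and pooled
    held-out ROC-AUC. A synthetic cohort generator with planted monotone
    feature-descriptor effects makes every stage testable without access
    to restricted cohort data, and an external-validation stage
    transfers binarization thresholds to a wide OAI-like table
    (exclusions, completeness filtering, correlation pruning,
    information-gain ranking, tuned SVM accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
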