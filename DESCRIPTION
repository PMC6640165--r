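Package: affectpipe
Title: Cognitive and Physiological Measurement Pipeline for Positive
    Activity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for pre/post writing-intervention
    studies that pair self-report well-being panels with cognitive task scores
    (recognition memory d-prime and criterion, situation construal, word find)
    and wearable physiology (EEG band-power and complexity features, heart-rate
    variability, electrodermal activity, skin temperature). Provides a
    synthetic-cohort generator with known ground-truth effects, event-locked
    EEG and autonomic feature extraction with amplitude/envelope artifact
    rejection, univariate change-score regressions with Bonferroni family
    control, and nested cross-validated classification of intervention
    condition with L1-regularized and tree-based model families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    signal,
    glmnet,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pracma
Config/testthat/edition: 3
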