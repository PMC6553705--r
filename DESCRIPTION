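Package: netwell
Title: Communication-Network Structure, Wearable Behavior, and Wellness Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weekly undirected communication networks and wearable-derived
    behavioral feature tables from raw event and minute-level streams, quantifies
    the coupling between network structure and health behavior via zero-lag
    normalized cross-correlation with thresholded counting and multiplicity-corrected
    high/low tests, and predicts ordinal wellness states (stress, happiness,
    positive attitude, self-assessed health) with a weighted-voting ensemble over
    tuned base classifiers. Includes a synthetic-cohort simulator with planted
    structure-behavior coupling so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    nnet,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
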