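Package: stateshift
Title: Boolean Network Modelling of Glioblastoma Cell-State Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning signed, directed protein-interaction networks
    annotated with per-cell-state activity into executable Boolean models and
    cell-state-transition hypotheses. Logic rules are synthesized so that each
    malignant cell-state profile (MES, AC, NPC, OPC) is a fixed point of the
    model; in-silico knockout screens measure how single-node clamps shift the
    network between states (Hamming distance, similarity, per-state z-scores);
    reference-based deconvolution and footprint activity inference map bulk
    cohorts onto dominant states; simulation-trained classifiers with additive
    tree-Shapley attributions flag clinically plausible transitions; and a
    synthetic-data module generates ground-truth models, single-cell and bulk
    counts, regulon statistics and paired booleanized profiles for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    glmnet,
    randomForest,
    xgboost,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    data.table
Config/testthat/edition: 3
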