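Package: spinecog
Title: Dendritic Spine Morphometry and Episodic Memory Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline relating dendritic spine
    morphology in human cortex to episodic memory performance. Generates
    synthetic neuropathology-cognition cohorts with per-spine geometry,
    measures and classifies spines (thin, stubby, mushroom, filopodia) from
    backbone reconstructions, aggregates per-case spine traits, selects
    memory-associated traits by L1-penalized regression with repeated
    cross-validated penalty selection, compares nested linear models by
    leave-one-out cross-validation with bootstrap mean-squared-error
    intervals, and screens feature-score associations with Spearman
    correlations under Storey q-value false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
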