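Package: clockforge
Title: Cross-Species Epigenetic Clocks from CpG Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates epigenetic clocks from methylation beta
    matrices: single-species chronological-age clocks and dual-species
    clocks for chronological age (via a log-linear age transform) and
    relative age (age divided by species maximum lifespan), all fit by
    elastic-net regression with internally cross-validated penalty
    selection. Includes leave-one-out and stratified k-fold external
    cross-validation, cross-species transfer evaluation (rank-order
    accuracy versus calibration), an epigenome-wide association screen of
    age with correlation-test Z statistics and Stouffer meta-analysis
    across tissues, array quality-control steps (inter-array correlation
    clustering, sex-mismatch flagging, random-forest out-of-bag trait
    prediction), a multi-species synthetic methylation panel generator
    with known ground truth, and a reproducible end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    randomForest,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
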