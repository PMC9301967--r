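Package: proteasekit
Title: Analysis of Protease Activity Screens and Activity-Based Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for building and querying enzyme-substrate activity
    databases, analysing in vitro fluorogenic peptide substrate screens
    (initial rates, fold changes, specificity-versus-efficiency scoring,
    bidirectional hierarchical clustering, rank correlation), and analysing
    in vivo activity-based nanosensor reporter data (normalisation,
    differential enrichment, principal component analysis, cross-validated
    classification, recursive feature elimination). Includes seeded
    synthetic-data generators for every supported input kind so that all
    analyses can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    pheatmap,
    e1071,
    randomForest,
    glmnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
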