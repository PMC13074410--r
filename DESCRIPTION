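Package: bloomthin
Title: Blossom-Thinning Simulation and Early Yield Prediction from
    Flowering-Stage Mask Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analyse binary flower-mask images of fruit-tree canopies for
    early (flowering-stage) yield prediction. Implements an adaptive
    multi-scale density clustering algorithm (KD-tree accelerated DBSCAN
    with a double-level, area-adaptive neighbourhood radius) that
    identifies flower clusters and the single flowers inside them; two
    blossom-thinning simulation strategies (density-graded dynamic
    retention and spatially uniform single-flower retention); a 50-feature
    flowering phenotype table organised in named feature groups; and a
    Lasso feature-selection plus regression-panel harness with k-fold
    cross-validated evaluation. A synthetic canopy generator with known
    cluster, flower and yield ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    glmnet,
    xgboost,
    randomForest,
    e1071,
    nnet,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
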