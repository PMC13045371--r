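Package: gcnsp
Title: Graph Convolution with Trainable Sparse Pooling for Multi-Site
    Connectome Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements graph convolutional networks with trainable sparse
    pooling (GCNSP) for case/control classification of functional-connectivity
    graphs pooled across imaging sites. Provides construction of Fisher-z
    connectivity matrices and the shared population K-nearest-neighbour graph,
    site-effect regression, the two-layer graph convolution with hierarchical
    sparse-pooling readout and its composite (cross-entropy + L1 + L2) loss,
    multi-site pooling cross-validation, leave-site-out testing, leave-site-out
    transfer learning with fine-tuning and optimal-epoch selection, recursive
    feature elimination baselines, class-activation-map interpretability down
    to single edges, group-difference t/KDE summaries, graph-shuffle controls,
    and a seeded generator of synthetic multi-site connectome datasets with
    planted discriminative edges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
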