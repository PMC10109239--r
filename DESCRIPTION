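Package: sdgae
Title: Drug-Target Interaction Prediction with a Spatially Consistent
    Graph Convolutional Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions from a heterogeneous
    drug-target network. Multiple similarity views (chemical structure,
    sequence, interaction profiles, disease and side-effect associations)
    are fused by elementwise maximum, the sparse interaction matrix is
    densified with a weighted K-nearest-known-neighbours imputation, and
    drug/target embeddings are learned with a two-layer graph
    convolutional autoencoder whose loss combines adjacency
    reconstruction, a Laplacian spatial-consistency penalty that
    preserves nearest-neighbour topology, and an optional adversarial
    regulariser pulling embeddings towards a Gaussian reference.
    Interaction propensities for all drug-target pairs are scored with a
    gradient-boosted tree ensemble. Includes a synthetic benchmark
    generator with planted cluster structure, 10-fold cross-validation
    with AUC/AUPR/top-ranked recall metrics, ablation harnesses, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pheatmap,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
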