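Package: gclda
Title: Geometric-Complement Network Prediction of lncRNA-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts long non-coding RNA (lncRNA)-disease associations from a
    tripartite heterogeneous network. Known lncRNA-miRNA interactions and
    miRNA-disease associations are propagated into the lncRNA-disease adjacency
    matrix by a geometric-complement score; Jaccard and Gaussian interaction
    profile kernel similarities over the association profiles are fused by
    elementwise maximum; per-entity features are compressed with a
    single-hidden-layer autoencoder; and a balanced random-forest classifier
    scores unobserved lncRNA-disease pairs. Includes stratified cross-validated
    evaluation (AUC, AUPR, recall, accuracy, F1), candidate ranking per disease,
    a planted-structure synthetic network generator for end-to-end testing, and
    a latent-dimension sweep harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ranger,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
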