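Package: manlink
Title: Link Prediction on Heterogeneous Molecular Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a typed heterogeneous molecular association network over
    miRNA, lncRNA, protein, drug and disease nodes, represents every node by
    a 64-dimensional attribute vector (3-mer sequence composition, MeSH-style
    disease semantic similarity, Morgan fingerprints, compressed by a stacked
    autoencoder) fused with a 64-dimensional behavior vector from a
    second-order LINE network embedding, and predicts unobserved associations
    of any of nine types with a random forest under leak-safe k-fold
    cross-validation. Includes seeded synthetic-data generators with planted
    latent structure for end-to-end evaluation without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ranger,
    rpart,
    e1071,
    xgboost,
    Biostrings,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
SystemRequirements: Open Babel (the obabel executable)
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
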