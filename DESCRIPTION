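Package: wsrcppi
Title: Sequence-Based Protein-Protein Interaction Prediction with Global
    Encoding and Weighted Sparse Representation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts protein-protein interactions from amino-acid sequence
    alone. Each protein is summarized by a global-encoding descriptor:
    residues are reduced to six physicochemical classes, the sequence is
    binarized under ten complementary three-versus-three class modes,
    prefix-partitioned into L subsequences, and each subsequence is
    described by its 0/1 composition and its adjacent-switch (transition)
    count, giving a 10*L*3-dimensional vector per protein (150 at L = 5).
    Protein pairs are classified by a weighted sparse representation
    classifier: the pair vector is reconstructed as a sparse linear
    combination of training pairs under Gaussian locality weights, and
    assigned to the class (interacting or not) with the smallest
    reconstruction residual. Includes a synthetic benchmark generator with
    a planted class-composition signal, k-fold cross-validation and
    cross-species evaluation protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
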