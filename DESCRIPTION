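Package: ehrmtl
Title: Multitask Neural Phenotyping on Sparse EHR Code Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when multitask learning helps supervised
    electronic phenotyping. Provides a seed-controlled synthetic generator for
    sparse binary medical-code cohorts with rule-defined rare phenotypes and
    correlated phecode-style auxiliary labels; single-task and multitask
    feed-forward neural networks with hard parameter sharing, batch
    normalization, Adam and early stopping; an L1-regularized logistic
    regression baseline; stratified repeated splitting and average-precision
    (AUPRC) evaluation; and information-theoretic phenotype-complexity
    statistics (entropy and Kullback-Leibler divergence over hashed
    oracle-feature combinations).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
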