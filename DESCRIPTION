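Package: batchgan
Title: Two-Stage Adversarial Batch Effect Removal for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Removes batch effects from single-cell RNA-seq expression
    profiles in two stages. Stage one trains a batch-conditioned
    autoencoder (encoder plus two generators under reconstruction and
    content losses) to learn low-dimensional, batch-ignorant content
    codes for every cell. Stage two finds mutual-nearest-neighbour cell
    pairs between batches in code space, expands them by within-batch
    random walks, and trains a residual generator against a Wasserstein
    critic with gradient penalty on those pairs only, so that whole
    batches can be transformed into the style of an uncorrected anchor
    batch. Includes readers and writers for common expression matrix
    formats, the standard preprocessing steps (QC filtering, log-TPM
    transform, shared-gene restriction, per-batch highly variable gene
    selection), a single-cell-level batch-mixing evaluation metric
    based on neighbourhood purity and a three-sigma batch-composition
    rule, probe-classifier gene-importance scores, and a seeded
    multi-batch count simulator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rhdf5
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
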