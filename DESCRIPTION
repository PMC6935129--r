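Package: tumorhet
Title: Single-Cell Heterogeneity Analysis of Mammary Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a droplet single-cell RNA-seq
    heterogeneity pipeline for mouse mammary tumors: UMI quantification with
    one-mismatch collapsing, rank-based cell calling, scale-factor
    normalization, highly-variable-gene selection, PCA, model-based
    clustering by Gaussian mixtures with constrained covariance
    parameterizations selected by minimal BIC, one-vs-rest Wilcoxon marker
    enrichment, marker-panel supercluster annotation with multiplet
    flagging, EMT and S100a4 positivity scoring, and PIK3CA/TP53 alteration
    co-occurrence analysis. A synthetic-data generator emulates the droplet
    data (lineage programs, ambient-only empty droplets, cross-lineage
    doublets, planted expression programs) so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
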