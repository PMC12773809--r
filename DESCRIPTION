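Package: topomics
Title: Multi-Omics Integration and Network Topology Analysis for Disease
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative classification of two-group cohorts from multi-omics
    data (DNA methylation M-values, RNA-seq counts, log-intensity proteomics).
    Implements block-wise preprocessing (M-value transform, median-of-ratios
    size factors, variance filtering, median centering, train-fitted scaling),
    sparse partial least squares discriminant analysis and its multiblock
    (DIABLO-style) extension with exact-cardinality keepX sparsity, balanced
    error rate tuning under repeated stratified cross-validation, bootstrap
    feature-selection stability, seed expansion on protein interaction
    networks (hypergeometric over-connectivity and random-walk-with-restart
    propagation with permutation nulls), a four-pillar network stability
    suite (robustness, criticality, structural metrics, regulator statistics),
    and gradient-boosted tree classification with bootstrap confidence
    intervals. A synthetic-data module generates multi-omics cohorts and
    scale-free interaction networks with planted signatures and regulators so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
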