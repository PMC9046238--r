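Package: nichecluster
Title: Robust Multi-Dataset Single-Cell Subclustering and Cluster Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for robust characterisation of cell subpopulations across
    multiple single-cell RNA-seq datasets. Implements iterative
    divide-and-conquer subclustering bounded by a high-resolution Louvain
    reference, bootstrap random-forest quantification of cluster stability
    with dissolution and reassignment of non-robust clusters, dataset-mixing
    Shannon entropy, Wilcoxon rank-sum marker detection with added-value
    analysis across datasets, signature-based annotation, hypergeometric
    over-representation testing, and a cross-species marker conservation
    enrichment score. Ships a negative-binomial synthetic-data generator with
    planted hierarchical cluster structure, batch effects and QC-relevant gene
    classes so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    ranger,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
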