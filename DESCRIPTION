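Package: coreactnet
Title: Co-Reactivation Network Analysis of Activity-Tagged Neuronal Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-epoch activity-tagging experiments in
    which neurons active during learning (e.g. TRAP2/TdTomato) and during
    memory retrieval (c-Fos) are counted per brain region and animal.
    Computes labeling fractions, chance-level overlap under independence,
    observed-over-chance reactivation ratios, and globally FDR-adjusted
    p-values; builds group-wise region-by-region Pearson co-reactivation
    matrices and signed weighted networks; derives centralities (strength,
    eigenvector, betweenness, closeness), clustering coefficients, hub sets,
    modularity-optimised communities, and global/local efficiency, including
    in-silico hub-deletion comparisons; performs group-label permutation
    tests for edge, centrality, and anatomical-group connectivity
    differences; and generates synthetic tagged-cell count datasets with
    known ground truth via a Gaussian copula on labeling rates.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
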