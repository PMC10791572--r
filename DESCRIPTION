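Package: scQA
Title: Dual-Perspective Cell Type Identification for Single-Cell
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies cell types in single-cell RNA-seq data from two
    complementary perspectives without a preset number of clusters.
    Genes are clustered into landmarks twice: qualitatively, from binary
    dropout patterns, and quantitatively, from binned
    quasi-trend-preserved expression profiles. Cells are then clustered
    by a seeded, bidirectional, two-hop label-propagation strategy on a
    directed k-nearest-neighbour cell graph built from the landmark
    matrices, yielding both cell clusters and cluster-associated key
    genes. Includes external validation metrics (ARI, NMI, FMI, JI), a
    planted-partition synthetic data generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
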