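Package: walktype
Title: Cell-Type Labeling for Single-Cell ATAC-Seq by Graph Diffusion
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates single-cell chromatin accessibility (scATAC-seq)
    cell-to-cell similarity with marker-gene-derived cell-type labels in a
    single weighted network, diffuses information through the network with a
    random walk with restarts, and uses the resulting global influence matrix
    to label cells (with ambiguity calls), cluster labels, and map bulk
    genomic regions to cell types. Includes a tunable label edge weight
    selected by maximizing cell homogeneity, annotation statistics
    (progression scores, region-score correlations, a region-permutation
    bimodality test, and nearest-gene resampling enrichment with
    Benjamini-Hochberg FDR), and a synthetic scATAC-seq data generator so
    every stage of the pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
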