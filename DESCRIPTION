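Package: creglink
Title: Comparative Single-Cell Multiome Analysis of CRE-Gene Linkages
Version: 0.1.0
Authors@R: person("Compass", "Reimplementation", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for comparative analysis of gene
    regulation from single-cell multiome (joint RNA + ATAC) data. Provides
    per-cell quality control (nucleosome signal, TSS enrichment, six-criteria
    filtering), RNA and ATAC normalization (log-normalization, TF-IDF),
    dimensionality reduction (PCA, LSI), joint SNN clustering with Louvain
    community detection, correlation-based cell-type annotation against
    reference pseudobulks, CRE-gene linkage scoring with a matched-background
    z-test, cross-sample comparison through a union CRE coordinate system
    (tissue-presence statistics, tissue-specific gene-linked CREs, region
    views), transcription factor peak-overlap enrichment, and a synthetic
    multiome corpus generator with planted ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
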