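Package: stemscore
Title: Chromatin Stemness Scoring for Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates a per-cell chromatin stemness score for glioma
    single-cell ATAC-seq data. Marker genes predictive of neural
    stem/progenitor cell states are selected by a consensus protocol over
    repeated runs of three tree-ensemble classifiers applied to labeled
    scRNA-seq data. Promoter and enhancer regions of the selected genes
    are linked to ATAC peaks by a strand-agnostic midpoint-in-peak test,
    peak counts are aggregated per gene and cell, lowly accessible cells
    are zeroed by a per-gene z-score filter, and the stemness score is a
    weighted sum of log-transformed gene accessibilities, min-max
    normalized to [0, 1]. Downstream helpers assign cells to glioblastoma
    cellular states from signature-gene accessibility via hierarchical
    clustering, and to glioma stem-cell functional states from bulk-ATAC
    discriminating regions. A synthetic-data generator with planted
    stem-like signal makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    methods,
    randomForest,
    stats,
    utils,
    xgboost,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
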