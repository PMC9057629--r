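Package: tilstrat
Title: Prognostic Stratification of Tumor Cohorts by Tumor-Infiltrating
    T-Cell Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline from multiplexed single-cell T-cell data to
    prognostic stratification of bulk tumor cohorts: hashtag-oligo (HTO)
    demultiplexing of cell barcodes, CLR normalization and cluster-level
    profiling of antibody-derived tags (ADT) with Pearson and gene-set-based
    linkage of stimulated to nonstimulated clusters, derivation of cluster
    marker and co-expression gene signatures from single-cell expression,
    TCR clonotype expansion and sharing statistics, per-patient preranked
    gene-set enrichment with a permutation null, and Kaplan-Meier /
    log-rank comparison of signature-enriched versus -depleted patients.
    Includes a synthetic-data generator producing multiplexed droplet runs
    and bulk survival cohorts with known ground truth so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    methods,
    survival
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    jsonlite
Config/testthat/edition: 3
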