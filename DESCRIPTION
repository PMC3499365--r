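Package: lncstab
Title: Selective Stabilization of Long Noncoding RNAs upon Nuclear
    Poly(A)-Binding Protein Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for the RNA-seq analysis that detects
    selective stabilization of long noncoding RNAs (lncRNAs) after
    depletion of the nuclear poly(A)-binding protein PABPN1. Builds
    coding and lncRNA gene catalogs from multi-source annotations with
    redundancy removal and maximal-locus construction, quantifies
    expression as RPKM over exonic unions, calls fold changes between
    depleted and control libraries, tests fold-change distribution
    asymmetry (sample skewness, D'Agostino K-squared, Kolmogorov-Smirnov,
    chi-squared, Fisher's exact, Student's t), classifies lncRNAs by
    strand-aware proximity and orientation relative to the nearest
    expressed coding-gene transcription start site, quantifies
    proximal/distal poly(A)-site usage shifts in 3'UTRs, scans for
    poly(A)-signal hexamers, fits first-order RNA decay from
    transcription-shutoff time courses, and computes qPCR, ChIP, and
    RNA-IP enrichment conventions. Seeded generators produce synthetic
    annotation, count, APA, decay, and qPCR data with ground-truth
    manifests for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
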