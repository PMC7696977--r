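Package: retroreg
Title: Regulatory Genomics of Transposable-Element Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transposable-element (TE) expression at the family and
    locus level from multi-mapped read alignments, builds strand-aware binned
    signal metaprofiles over repeat loci, tests per-family enrichment of
    transcription-factor and chromatin peaks, scans peak-summit windows for the
    canonical E-box motif and compares bound versus unbound loci, thresholds
    differential-expression tables with Benjamini-Hochberg control, tests
    gene-set overlaps, and screens LTR neighborhoods for enhancer-candidate
    genes. Family expression uses an exclusive-family rule for multi-mapping
    reads; locus expression redistributes multi-mappers by
    expectation-maximization anchored on uniquely mapped reads. A seeded
    synthetic-data module generates every pipeline input with planted ground
    truth for parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
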