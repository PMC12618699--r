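Package: scSplitPool
Title: Split-Pool Single-Cell ATAC Processing for FFPE Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing split-pool combinatorially indexed
    single-cell ATAC-seq data from formalin-fixed paraffin-embedded (FFPE)
    tissue. Implements birthday-paradox barcode collision estimation,
    linker-anchored demultiplexing of staggered barcode reads with
    last-5-base rescue, duplicate collapsing for combined PCR and linear
    (in vitro transcription) amplification, per-cell quality control
    (FRiT, FRiP, TSS profiles, fragment-length bands) and cell filtering,
    pseudo-bulk resampling differential accessibility with
    Benjamini-Hochberg correction and fold-change gates, and a bootstrap
    robustness layer for pseudotime lineage inference. Ships a seeded
    synthetic-data generator (genome, cells, FFPE-length fragments,
    paired FASTQ with ground truth) so the whole pipeline is testable
    without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
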