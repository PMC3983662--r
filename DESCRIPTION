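Package: peakscape
Title: Downstream Analysis of Multi-Subunit Protein Complex ChIP-seq
Version: 0.1.0
Authors@R: person("Peakscape", "Developers", role = c("aut", "cre"),
    email = "peakscape@example.org")
Description: A reusable downstream pipeline for ChIP-seq of multi-subunit
    chromosomal protein complexes (condensin I, I-DC and II in Caenorhabditis
    elegans and similar systems): per-base coverage normalization to the
    genome-wide median, input subtraction, replicate merging and background
    z-scoring; consensus peak construction from k-of-n subunit peak sets with
    summit calling and valley-based peak splitting; permutation (shuffle)
    tests for overlap enrichment against genomic annotations and transcription
    factor sites; anchored signal and GC-content profiles around transcription
    start sites and peak summits; integration of binding with gene expression
    and differential-expression calls; position-weight-matrix motif scanning
    with motif-context statistics; window-level chromatin feature matrices
    with correlation clustering and permutation feature importance. A
    synthetic-data generator emulates the full input bundle (genome, tracks,
    peaks, expression, motifs) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
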