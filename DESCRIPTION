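Package: iestools
Title: Analysis of Programmed DNA Elimination in Paramecium from Gapped
    Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying internal eliminated sequence (IES) excision
    during macronuclear development in ciliates. Computes per-IES retention
    scores from boundary-spanning read counts, detects and classifies
    excision events at canonical, alternative and cryptic TA boundaries from
    gapped alignments to a germline-inclusive (MAC+IES) reference, derives
    excision-length and boundary-offset statistics including the "forbidden"
    length-peak mass, and profiles DNA-seq-normalized nucleosome densities
    across IESs with retention-stratified Kolmogorov-Smirnov comparisons.
    A synthetic-data module generates toy genomes, annotations, DNA-seq
    reads and nucleosomal fragments with known ground truth so that every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
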