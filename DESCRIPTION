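Package: endguide
Title: End-Guided Transcript Isoform Assembly from End-Labeled RNA-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects RNA 5' and 3' end labels left by template-switching and
    oligo-dT priming in RNA-seq reads, stores aligned reads in a compact
    end-labeled read (ELR) text format, and assembles full-length transcript
    isoforms per locus as greedy source-to-sink paths through an overlap graph
    whose boundaries are clustered Start/Cap/End Tags and coverage-filtered
    splice junctions. Includes artifact filters for high-error long-read exons
    and oligo-dT mispriming, a condense/meta-assembly mode for single-cell
    data, and a ground-truth read simulator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
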