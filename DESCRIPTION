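Package: longform
Title: Isoform Detection and Quantification from Full-Length Nanopore cDNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for full-length cDNA long reads: demultiplexes
    single cells by 60-nt indexes, trims ISPCR adaptors, filters spliced
    genome alignments (PSL) to one alignment per read, quantifies gene and
    transcript expression as reads per gene per 10,000 aligned reads
    (RPG10K), detects transcription start/end sites and splice sites as
    20-bp genomic bins, calls alternative splice site usage, intron
    retention and exon skipping, groups reads into isoforms with
    partial-order-alignment consensus sequences, and tests differential
    isoform usage across cells with chi-square contingency tests under
    Holm-Sidak multiple-testing correction. Includes a seeded simulator of
    multi-isoform gene loci, error-bearing full-length cDNA reads and
    ground-truth alignments for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
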