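Package: ghrecover
Title: Targeted Recovery of Glycoside Hydrolase Genes from Metagenomic
    Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A homology-guided, gene-centric assembly pipeline for recovering
    glycoside hydrolase (GH) family genes from single-end metagenomic short
    reads such as 454 pyrosequencing data. Reads homologous to a reference
    protein panel are recruited by six-frame translated local alignment with
    Karlin-Altschul e-value statistics, assembled by a greedy
    overlap-layout-consensus assembler, iteratively extended from contig ends
    against the full read pool, annotated by ORF calling and translated
    best-hit family assignment, weighted by per-sample read depth, and
    validated by contig-specific primer design with in-silico PCR. A
    ground-truthed 454-style metagenome simulator with homopolymer-biased
    indel errors makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
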