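Package: amplitype
Title: HLA-B Genotyping from Multiplexed Nanopore Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotyping toolkit for barcoded long-read amplicon sequencing of the
    HLA-B locus. Covers the full desk-scale pipeline: an allele reference database
    with G-group construction and IUPAC-degenerate in-silico PCR; a nanopore-style
    read simulator with a repeat-aware indel error model; barcode demultiplexing by
    semi-global edit distance; read quality filtering and run statistics; a
    mismatch-minimising allele-pair genotyping engine with consensus calling,
    ambiguity flags, systematic-mismatch hotspot detection and repeat-masked
    rescoring; and cohort-level allele frequency and pharmacogenetic risk-allele
    reporting. User-facing functions take and return tibbles so stages compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
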