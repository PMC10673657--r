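Package: phasikit
Title: Detection and Annotation of Phased Secondary siRNA (phasiRNA) Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for discovering PHAS loci from small-RNA
    sequencing data: repeat filtering and read collapsing, exact genome
    mapping, phase-register accounting with the 2-nt antisense offset, a
    sliding-window hypergeometric test and per-position phase score, locus
    extension/merging/FDR correction and naming, degradome (PARE) validation
    of miRNA triggers and phasiRNA targets with SeqTar-style filters,
    TAS3-like locus annotation via conserved tasiARFs, and regulatory-network
    export. Includes a synthetic-data generator that implants phased loci,
    duplex-partner reads, triggers with cleavage signatures and TAS3-like
    architectures so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    Rsamtools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
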