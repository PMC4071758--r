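Package: splicefate
Title: Splicing Fate of Multi-Exon Plant Genes: Event Classification, PTC
    Prediction, and Intron-Position Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies alternative-splicing forms of transcripts against a
    canonical gene model (intron retention, exon skipping, alternative 5'/3'
    splice-site selection, and combinations), predicts the protein consequence
    of each form (premature termination codons, truncated or extended
    proteins, functional calls) together with candidate features of
    nonsense-mediated decay (upstream ORFs, long 3'UTRs, 3'UTR introns), and
    projects intron positions onto protein alignments in decimal-phase
    notation to identify conserved intron position classes across species and
    infer intron losses on a species tree by Dollo parsimony. Includes a
    seeded synthetic gene-structure simulator that generates gene models,
    labelled splice variants, planted-conservation alignments, and species
    trees for validation, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
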