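Package: telltale
Title: Transposable Element Insertion Calling and Allele Frequency
    Estimation from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transposable element (TE) insertions and deletions from
    long-read sequencing data by combining two complementary tracks: an
    assembly-to-reference comparison that recovers high-frequency ("insider")
    insertions already incorporated into the sample assembly, and a
    read-to-assembly mapping track that recovers low-frequency ("outsider")
    insertions from large insertion operations and soft-clipped read ends.
    Candidate sequences are annotated against a TE consensus library under the
    80/80 identity/length-coverage rule, target site duplications are detected
    from junction flanks and used to refine insertion breakpoints, and a
    per-insertion allele frequency is estimated from supporting reads over
    local read depth. Ships with a seeded synthetic benchmark generator that
    plants TE insertions with target site duplications across haplotype pools
    and mixes reads at chosen depths, plus precision/recall scoring of call
    sets against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: BLAST+ (blastn, makeblastdb) on the PATH
Config/testthat/edition: 3
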