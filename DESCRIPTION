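Package: rdnafinish
Title: rDNA-Operon-Aware Planning for Bacterial Genome Finishing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning and analysis toolkit for finishing fragmented bacterial
    draft genomes whose assembly is broken by repetitive ribosomal RNA (rDNA)
    operons. From a draft assembly (and optionally a finished reference
    genome) it masks rRNA-only contigs, locates ambiguous-base (N) stretches
    and designs flanking primers, places small contigs into N-stretches,
    orders and orients contigs against the reference, classifies inter-contig
    gaps by rDNA content using universal 16S/23S primers, emits the parallel
    six-reaction primer-walking plan for rDNA gaps, detects large assembly
    rearrangements, and validates a finished sequence against the original
    draft. Wet-lab PCR and Sanger steps are replaced throughout by in-silico
    PCR and read-span simulation. Includes a fully seeded synthetic genome
    and draft-corruption simulator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
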