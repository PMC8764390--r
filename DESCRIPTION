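Package: retrodup
Title: Retroduplication and Tandem Duplication Analysis for Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for studying how RNA-based gene duplication
    (retroduplication) seeds later tandem duplication in plant genomes.
    Identifies retrogenes from intron loss and exon-junction evidence, detects
    intact LTR retrotransposons and genes they carry, dates insertions from
    terminal-repeat divergence (T = K/2mu), estimates Ka/Ks by the
    Nei-Gojobori (1986) method, classifies duplicate genes as
    tandem/proximal/dispersed/WGD, tests orthogroup expansion under a
    birth-death model, and summarises tandem-duplicate enrichment across
    retro-seeded versus plain orthogroups. Ships a seeded synthetic-genome
    generator that plants every event class with a machine-readable truth
    table, so every caller is benchmarked against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
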