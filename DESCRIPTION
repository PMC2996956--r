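Package: ssrsurvey
Title: Microsatellite Mining and Allelic Richness Surveys of Sequence Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects perfect simple sequence repeats (SSRs, microsatellites)
    in FASTA sequence libraries such as BAC-end and EST read sets, groups
    repeat units into cyclic-rotation motif classes, classifies SSR placement
    relative to open reading frames, and tests observed motif and ORF
    distributions against uniform and library-composition null models with
    chi-square goodness-of-fit tests. Also ingests genotype screening tables,
    applies amplification filters, and relates allelic richness to reference
    repeat number and motif base composition with nonparametric statistics.
    A synthetic-data module generates read libraries with planted repeats and
    genotype tables with known richness structure so every pipeline stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
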