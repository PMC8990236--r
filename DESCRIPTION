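Package: ferttx
Title: Multi-Assay Transcription Characterization of Fertility Genes
Version: 0.1.0
Authors@R:
    person("Repro", "Transcriptomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing gene transcription from three
    complementary expression assays in cattle: heterozygous-site calling and
    haplotype-level genome divergence from whole-genome-sequencing allele
    counts, a two-stage Pearson chi-squared test of allele-specific
    expression with a WGS-ratio-corrected null, reads-per-million expression
    quantification across RNA-seq, CAGE-seq and ISO-seq, CAGE tag-cluster
    peak calling with 5' UTR length derivation, and exon-chain
    classification of long-read isoforms (novel junctions, intron
    retention, UTR-only terminal variants, nested antisense exons). A
    seeded synthetic-data generator with a machine-readable truth record
    makes every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
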