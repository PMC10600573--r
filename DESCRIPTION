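Package: promoterforge
Title: Mining Stable Promoters from Transcriptome Counts and Engineering
    dCas9-Repressible NOR-Gate Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying constitutively expressed genes from
    gene-level RNA-seq count matrices via median-of-ratios normalization and
    coefficient-of-variation ranking, extracting promoter+5'UTR and
    3'UTR+terminator parts from a genome and annotation under
    neighbour-truncation rules, screening parts for Golden Gate (MoClo)
    domestication, scanning promoters with position weight matrices for
    predicted transcription-factor binding sites, placing pairs of
    genome-orthogonal gRNA target sites into motif-free promoter windows to
    create NOR-gate promoters, and analysing ratio-metric plate-reader
    fluorescence assays (Dunnett many-to-one comparisons, Tukey HSD with
    compact letter displays, and fold-repression estimates). Includes seeded
    synthetic-data generators (toy genomes, negative-binomial count matrices,
    motif libraries, plate tables) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    DESeq2
Config/testthat/edition: 3
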