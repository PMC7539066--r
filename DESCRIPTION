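Package: splicescape
Title: Alternative Splicing Event Characterization from Multi-Isoform Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterizes alternative splicing (AS) in a multi-isoform
    transcriptome from a genome FASTA, a GTF/GFF3 annotation and tissue-level
    FPKM matrices. Enumerates and deduplicates the seven basic AS event types
    (intron retention, exon skipping, alternative 5'/3' splice sites,
    alternative first/last exons, mutually exclusive exons) by pairwise
    isoform comparison; classifies expressed intron-retaining transcripts as
    PTC-containing or not relative to a reference ORF; profiles intron
    terminal dinucleotides for AS versus non-AS genes; computes gene-structure
    statistics and their relationship with AS frequency and event type; and
    builds a simplified signed weighted coexpression network with module
    detection and top-degree hub calling. A seeded synthetic-transcriptome
    generator plants events, splice sites, PTC statuses and coexpression
    modules with machine-readable truth tables for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
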