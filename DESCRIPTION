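Package: chipfrag
Title: Sequence Characterization of ChIP-Derived DNA Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico characterization of cloned chromatin
    immunoprecipitation (ChIP) DNA fragments. Expands IUPAC-degenerate
    consensus binding patterns into plain-sequence sets and scans genomes
    for exact occurrences with observed-versus-expected spacing statistics;
    compares fragment AT-content against a 500-bp windowed genome background
    with a Wilcoxon rank-sum test; finds conserved short segments shared
    between fragments with a word-seeded ungapped (blastn-short style)
    aligner and summarizes them as information-content sequence logos;
    quantifies ChIP-qPCR fold enrichment from threshold-cycle pairs; and
    classifies fragment loci against gene models into intragenic
    (exon/intron), intergenic (nearest gene, up/downstream, distance) and
    unplaced categories. A synthetic-data module generates genomes with
    controlled AT composition, planted motifs, AT-biased fragments, gene
    models and qPCR tables so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
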