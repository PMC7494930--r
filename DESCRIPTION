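Package: phagepop
Title: Comparative Genomics and Diversity Analysis of Phage Genome Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for alignment-free and gene-content based diversity analysis
    of assembled bacteriophage genomes. Computes canonical k-mer
    presence/absence profiles and binary (Jaccard) distance matrices, UPGMA
    dendrograms with cut-height cluster calling, ortholog gene-family
    clustering with Roary-style core/softcore/shell/cloud pan-genome
    partitions, marker-gene phylogenies (progressive alignment, Tamura-Nei
    distances, neighbor joining, bootstrap supports), Robinson-Foulds and
    branch-score tree agreement, gene-order locally collinear block (synteny)
    detection, and ICTV-style genus assignment with new-genus flagging. A
    mosaic phage population simulator with recorded ground truth (clusters,
    gene families, rearrangement events) makes every stage testable without
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    mclust,
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
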