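Package: orthofam
Title: Comparative Gene-Family Analysis Across Genomes with
    Alignment-Free Phylogeny
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end comparative genomics of protein-coding gene
    content across a set of genomes: Markov clustering (MCL) of a gene
    similarity graph into ortholog groups, gene-family count matrices,
    partitioning of families into core, clade-specific, clade-diversified,
    species-expanded and species-specific sets, gene-family expansion
    statistics (grouped-binomial likelihood-ratio and one-sided Fisher
    exact tests with Benjamini-Hochberg FDR control), alignment-free
    whole-proteome phylogeny from length-8 feature frequency profiles
    compared by Jensen-Shannon divergence with neighbor-joining and
    feature bootstrap, and hypergeometric GO term enrichment.  Includes a
    synthetic-proteome generator that evolves gene families along a known
    species tree with birth/death, planted lineage-specific expansions and
    planted GO enrichment, so every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
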