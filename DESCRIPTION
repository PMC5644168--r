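Package: ssucensus
Title: Diversity Census of Full-Length SSU rRNA Genes by Two-Level
    Identity Clustering and Phylogenetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for diversity censuses of
    full-length small-subunit (SSU) rRNA gene alignments: quality
    filtering by ungapped length and gap content in an internal
    clustering window, greedy centroid clustering at 97% identity
    (species-like OTUs) linked to 85% identity clusters (order-level
    lineages), novelty categorisation against an amplicon reference
    database, reference-based two-parent chimera screening,
    neighbor-joining bootstrap phylogenies with iterative rogue-taxon
    removal and monophyly-based phylum assignment, phylogenetic
    diversity statistics, per-environment tallies, and in-silico
    primer-mismatch prediction for degenerate PCR primers.  A
    synthetic-community generator evolves phylum-structured sequence
    families along simulated trees with planted chimeras, truncated and
    gap-riddled sequences, and rogue lineages, emitting truth tables so
    that every pipeline stage can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
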