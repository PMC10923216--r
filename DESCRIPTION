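Package: microgill
Title: Diversity, Indicator and Co-Activity Network Analysis for Fish Gill Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable statistical pipeline for 16S rRNA transcript (activity)
    amplicon surveys of host-associated microbiota, built around the analysis
    chain used for Arctic char gill communities sampled across several Arctic
    sites: count filtering and relative-activity normalization, taxonomic
    aggregation, alpha diversity (Pielou evenness, Chao1 richness, Faith's
    phylogenetic diversity with a neighbor-joining tree builder), phylogenetic
    beta diversity (weighted and unweighted UniFrac) with PCoA and NMDS
    ordination, permutation inference (PERMANOVA, pairwise PERMANOVA,
    multivariate dispersion homogeneity, environmental vector fitting),
    indicator-taxon (IndVal) analysis, and per-site signed Spearman
    co-activity networks with topology metrics used as dysbiosis signatures.
    A logistic-normal community simulator with planted ground truth makes
    every stage testable without raw sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    igraph,
    jsonlite,
    yaml,
    phangorn,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    optparse
Config/testthat/edition: 3
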