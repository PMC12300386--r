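Package: ecoassembly
Title: Community Assembly Inference and Co-Occurrence Networks for
    Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diversity, dissimilarity and community-assembly inference for
    amplicon (ASV/OTU) count tables along environmental gradients, with a
    focus on salinity-structured aquatic habitats such as coastal
    groundwater and reservoirs.  Implements the Sloan neutral community
    model, null-model assembly partitioning based on the beta nearest
    taxon index (betaNTI) and the Bray-Curtis Raup-Crick index (RCbray),
    phylogenetic beta diversity (beta-MNTD, Faith's PD), SIMPER,
    PERMANOVA, (partial) Mantel and distance-decay analysis, Spearman
    co-occurrence networks with Zi-Pi role classification, relative
    modularity, robustness and natural-connectivity stability
    experiments, and a seeded synthetic-data generator that produces
    phylogenies, trait-structured metacommunities and multi-group count
    tables under controlled assembly regimes (niche selection, neutral
    drift, drifted pools).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    picante,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
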