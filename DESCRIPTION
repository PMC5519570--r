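Package: MicroMetacom
Title: Metacommunity Structure and Phylogenetic Beta Diversity for
    Host-Associated Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of host-associated microbial metacommunities from OTU
    count tables: abundance filtering, rarefaction, core-microbiome and
    alpha-diversity summaries; elements of metacommunity structure (EMS)
    inference by reciprocal averaging with coherence, species turnover and
    boundary-clumping statistics tested against fixed-proportional (r1)
    permutation nulls, including compartment splitting; phylogenetic and
    compositional beta diversity (unweighted and weighted UniFrac, Jaccard,
    PCoA, ANOSIM, PERMANOVA, Mantel tests against genetic and geographic
    distance); and a synthetic-data generator producing datasets with known
    metacommunity structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    vegan,
    ape,
    geosphere,
    biomformat,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phyloseq,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
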