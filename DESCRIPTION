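Package: phyloinvasion
Title: Community Phylogenetic Structure of Alien Floras Across Invasion Stages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the phylogenetic structure of alien plant
    communities along the invasion continuum (introduced, naturalized,
    invasive). Computes abundance-weighted and presence-based net
    relatedness (NRI) and nearest taxon (NTI) indices against a tip-shuffle
    null model, phylogenetic anomalies between full and status-defined
    communities, mega-tree grafting of species missing from a backbone
    phylogeny, spatial rarefaction of occurrence records, multi-scale
    community construction, and a downstream statistics layer (AICc model
    selection, two-way ANOVA with Holm-adjusted post hocs, climate
    regressions, Spearman correlations). A seeded synthetic-data generator
    produces trees, Brownian climate niches, region lattices, climate grids
    and climate-filtered occurrences so the full pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    geosphere,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
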