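Package: resurveydiv
Title: Diversity and Community Change from Paired Historical and Modern
    Vegetation Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for century-scale grassland resurvey analysis: pairing
    historical biomass records with modern cover estimates, computing
    taxonomic, functional and phylogenetic alpha/beta/gamma diversity via
    Rao's quadratic entropy with the Jost equivalent-number correction,
    community-weighted indicator values, Grime CSR strategy composition and
    taxonomic-group cover shares, and testing survey contrasts and their
    elevation dependence with linear mixed models. Includes a synthetic-data
    generator that emulates the hierarchical potential-area design of
    historical square-foot plot resurveys, with configurable
    elevation-dependent change signals and a stored ground truth, so every
    stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    lmerTest,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
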