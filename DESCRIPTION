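Package: phylofd
Title: Functional and Phylogenetic Diversity Effects on Forest Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking forest productivity to functional
    dispersion (FDis), phylogenetic species variability (PSV) and
    community-weighted mean traits (CWM) computed from forest-inventory
    basal areas, a species-level trait table and an ultrametric chronogram.
    Provides maximum-likelihood estimation of Pagel's lambda with
    parametric-bootstrap confidence intervals, Moran's I phylogenetic
    correlograms over patristic distance classes, adjusted-R-squared
    variance partitioning between functional and phylogenetic diversity
    with Freedman-Lane residual-permutation tests, and a synthetic-data
    generator (Yule chronograms, Brownian-motion traits, plot communities,
    productivity responses) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
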