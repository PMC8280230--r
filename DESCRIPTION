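Package: kelpbeta
Title: Hierarchical Beta Diversity of Paired eDNA and Visual-Census Fish Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the hierarchical spatial structure of reef fish
    communities surveyed jointly by eDNA metabarcoding of water samples and
    underwater visual census (UVC). Covers post-BLAST taxonomy curation of OTU
    tables (top-percent hit filtering, majority lowest-common-ancestor
    assignment, rank-threshold elevation, contaminant removal and hierarchical
    OTU merging), additive partitioning of regional taxonomic richness with
    individual-based randomization nulls, spatially ordered taxa-area curves
    with linear, exponential, power and one-breakpoint piecewise fits,
    Bray-Curtis distance decay with Mantel tests and simulation-based power
    curves, hierarchical variance partitioning of compositional dissimilarity,
    indicator-taxon analysis, and cross-method taxon harmonization. A synthetic
    landscape generator reproduces the nested site/transect/replicate sampling
    design so every stage can be exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
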