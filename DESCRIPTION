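Package: phylogaps
Title: Spatial Phylogenetic Diversity and Conservation Gap Analysis for
    Crop Wild Relatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based spatial phylogenetics and conservation gap
    assessment for crop wild relatives and other plant inventories.
    Aggregates occurrence records to a degree grid, computes per-cell
    species richness, sampling redundancy, Faith's phylogenetic
    diversity (PD) and relative phylogenetic diversity (RPD), tests
    observed values against a richness- and range-constrained
    (fixed-fixed) curveball randomization null, scores each species for
    ex-situ and in-situ conservation representativeness with priority
    categories, builds composite PD-gap and PD-richness indicator
    rasters, and summarizes protected-area representativeness of
    diversity hot spots by administrative region. Includes a synthetic
    data generator emulating clustered species ranges, uneven sampling
    effort, germplasm/reference record splits and blocky protected-area
    layers so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    geosphere,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
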