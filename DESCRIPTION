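Package: phylospace
Title: Spectral Density Profiles and Phylogenetic Space for
    Diversification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Non-parametric comparison of phylogenetic tree shape via the
    spectral density of the modified graph Laplacian (MGL). Computes
    spectral density profiles and their summary statistics (ln principal
    eigenvalue, skewness, peak height, eigengap modality), clusters trees
    into diversification types with Jensen-Shannon profile distances,
    maps trees into a three-dimensional phylogenetic space bounded by
    archetypes fitted with a minimal-volume enclosing polytope, charts
    the space available to trees with a constrained random-Laplacian
    sampler and a birth-death simulator with time-varying speciation
    rates, and traces average trajectories through that space over crown
    age using natural-breaks binning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    e1071,
    graphics,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
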