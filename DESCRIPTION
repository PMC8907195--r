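Package: hemiconn
Title: Graph-Theoretic Analysis of Hemispheric Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for weighted, region-labelled structural
    connectivity matrices of a single cerebral hemisphere, as used in
    paediatric perinatal-stroke connectomics. Provides density-based edge
    thresholding, nodal and hemispheric graph metrics (weighted betweenness
    centrality via shortest-path tallies, weighted clustering coefficients,
    hierarchical and neighbourhood complexity of degree sequences),
    Erdos-Renyi null-model ensembles, normality-gated group statistics with
    Bonferroni-corrected post hocs, brain-behaviour correlations, effect
    sizes and post-hoc power, and a seeded synthetic three-group cohort
    generator for end-to-end testing without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
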