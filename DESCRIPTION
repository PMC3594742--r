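Package: micanet
Title: Maximal Information Component Analysis for Gene Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene co-expression networks from the maximal information
    coefficient (MIC), a grid-based normalized mutual information measure that
    captures non-linear and gene-by-environment relationships missed by
    correlation networks. Network links are assigned to latent interaction
    components with a collapsed Gibbs sampler (ICMg), yielding fuzzy per-gene
    module memberships; modules are summarized by weighted-PCA eigengenes.
    Includes scale-free-topology fitting for soft and hard thresholding, a
    simplified correlation/TOM baseline, module-quality statistics (perplexity
    against ontology-derived gene classes, enrichment-based usefulness,
    Fisher-exact module stability, a non-linearity census), and synthetic-data
    generators with planted overlapping modules and condition-dependent
    relationships.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
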