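Package: granulecology
Title: Whole-Ecosystem Community Analysis of Replicate Methanogenic Granules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for microbiome experiments that treat single
    methanogenic granules as replicated whole ecosystems. Implements
    compositional (CLR-based) replicate-consistency screening, alpha and beta
    diversity with permutation PERMANOVA, per-genus negative-binomial
    condition-response modelling with resilient/susceptible classification,
    genetic-algorithm search for stable (minimum-CV) community ensembles,
    abundance-occupancy core ranking with a Bray-Curtis contribution stopping
    rule, Sloan neutral-assembly classification, Levins niche breadth and
    asymmetric niche overlap, and a Dirichlet-multinomial community simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    MASS,
    vegan,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
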