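Package: allomhb
Title: Hierarchical Bayesian Allometric Scaling for Trees and Branches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a four-trait multivariate power-law allometry model
    (branch length, aboveground mass, stem mass, leaf mass against
    diameter) with Berkson measurement error on diameter and three-level
    partial pooling (tree, species, global) by Metropolis-within-Gibbs
    MCMC. Includes a forward simulator matching the model's generative
    assumptions, preprocessing of raw branch-harvest records (dry-mass
    conversion, downstream biomass aggregation, minimum-diameter
    filtering), posterior predictive checks with Bayesian p-values, and
    scoring of Metabolic Scaling Theory, Geometric Similarity and Stress
    Similarity predictions by credible-interval inclusion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
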