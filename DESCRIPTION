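Package: jstdm
Title: Joint Species-Trait Distribution Modelling with Latent Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian hierarchical joint species-trait distribution model
    (JSTDM) in which each species contributes several response columns to a
    single multivariate model: presence-absence, abundance conditional on
    presence (hurdle structure), and site-level trait values that are
    structurally missing where the species is absent. A blocked Gibbs sampler
    with probit data augmentation and multiplicative-gamma shrinkage on latent
    factor loadings estimates environmental responses, trait-mediated expected
    responses, and the factor-induced association matrix among all
    species-by-response-type column units. Includes conditional prediction
    (the engine behind conditional cross-validation and focal-species scenario
    simulation), expected-richness summaries, k-fold baseline and conditional
    cross-validation, and a generative module producing synthetic communities
    from the exact model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
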