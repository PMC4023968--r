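Package: nichemod
Title: Trait-Modulated Gaussian Logistic Niche Models for Binary Community Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits hierarchical Bayesian Gaussian logistic (unimodal) species
    response models to presence-absence community tables, with the niche
    parameters of every species (optimum, tolerance and maximum occurrence
    probability) linearly modulated by species traits. Trait slopes carry a
    spike-and-slab prior (point mass at zero plus a double-exponential slab)
    so that unimportant traits are selected out exactly; the same variable
    selection machinery can estimate a sparse latent environmental gradient
    as a linear combination of measured environmental variables. Includes
    GLM-based starting-value machinery via the quadratic-logit
    reparameterization, deviance information criterion (DIC) reports with
    both effective-parameter estimators, trait-explained variance summaries,
    convergence diagnostics, a generative simulator for presence-absence
    communities, and post-fit utilities (response-curve prediction, species
    grouping by niche optimum, between-group trait tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse,
    yaml
Config/testthat/edition: 3
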