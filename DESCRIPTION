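Package: corevol
Title: Correlated Evolution of Functional Traits and Climatic Niches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing correlated evolution between continuous
    functional traits and climatic-niche variables on a phylogeny while
    propagating intraspecific trait variation and phylogenetic uncertainty.
    Includes hierarchical Bayesian estimation of species trait
    distributions from individual-level field measurements with a site
    random effect, probability-weighted climatic-niche occupancy profiles,
    maximum-likelihood fits of Brownian-motion, Ornstein-Uhlenbeck and
    white-noise models compared by small-sample AIC and Akaike weights,
    Bayesian tests of correlated evolution under bivariate Brownian motion
    with stepping-stone marginal likelihoods and log Bayes factors, a
    four-design uncertainty grid crossing trait draws with bootstrap
    trees, and distance-based dendrograms of evolutionary correlation
    matrices. A synthetic-data generator simulates trees, correlated trait
    evolution, individual observations and occupancy surfaces so the whole
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
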