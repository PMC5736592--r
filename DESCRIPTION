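Package: isonet
Title: Social Isolation Metrics and Their Repeatability from Grooming
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying persistent social isolation in
    group-living animals from focal-sampling observation data.  Builds
    directed, weighted grooming-rate networks per social group and year,
    computes five isolation metrics (instrength, outstrength, weighted
    betweenness, clustering coefficient, eigenvector centrality) with
    within group-year z-scores, derives dominance rank (David's score),
    close-kin counts from a pedigree, and male group tenure, and
    decomposes metric variance with a conjugate Gibbs sampler for
    Gaussian mixed models with multiple random intercepts, reporting
    repeatability, maternal, group, year and natal-group variance
    proportions and fixed effects with MCMC p-values.  A synthetic
    focal-sampling data generator with known variance components makes
    every pipeline stage testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
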