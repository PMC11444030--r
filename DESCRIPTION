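Package: crtmediate
Title: Causal Mediation Analysis for Cluster-Randomized Sanitation Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes the effect of a cluster-randomized sanitation
    intervention on child diarrhea into pathways through latrine quality,
    latrine use, and feces management mediators. Implements the
    counterfactual average causal mediation effect (ACME) and average
    direct effect (ADE) on the prevalence-difference scale via
    quasi-Bayesian Monte Carlo simulation with block-clustered sandwich
    covariance, a varying-coefficient linear structural-equation estimator
    with cluster bootstrap for mediators subject to post-treatment
    confounding, log-binomial/modified-Poisson/proportional-odds screening
    models with cluster-robust variance, rainfall-based monsoon season
    segmentation, polychoric mediator correlations, and a synthetic
    cluster-randomized trial generator with a brute-force counterfactual
    oracle for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mvtnorm,
    numDeriv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
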