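Package: microdbn
Title: Two-Slice Conditional Gaussian Dynamic Bayesian Networks for
    Longitudinal Microbiome Compositions
Version: 0.1.0
Authors@R:
    person("Maintainer", "microdbn", email = "microdbn@example.org",
           role = c("aut", "cre"))
Description: Learns two-slice dynamic Bayesian networks over longitudinal
    microbial relative-abundance profiles and clinical covariates using
    conditional linear Gaussian families with conjugate
    normal-inverse-gamma scoring and Dirichlet-multinomial evidence for
    discrete nodes.  Provides greedy hill-climbing structure search with
    edge-wise Bayes factors, one-step compositional prediction with
    leave-one-subject-out and k-fold evaluation protocols, posterior
    likelihood scoring of abrupt compositional shifts (abruptions),
    iterative forward simulation of microbiome trajectories from measured
    or synthetic initial conditions, and a seeded synthetic-cohort
    generator with a known ground-truth model for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
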