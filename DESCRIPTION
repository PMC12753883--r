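Package: adviceRL
Title: Reinforcement-Learning Models of Advice-Taking Under Phrasing and
    Framing Manipulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a probabilistic two-card decision task with
    trial-by-trial advice, implements a family of eight delta-rule
    reinforcement-learning models that combine self-learning and
    advice-learning through an advice reference weight, fits them by
    hierarchical Bayesian MCMC, compares them by PSIS-LOO (LOOIC),
    validates fits with trial-wise posterior predictive checks, and
    provides the condition-level statistics (paired t-tests, repeated
    measures and mixed-design ANOVA) used to analyse phrasing and
    framing effects on advice integration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
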