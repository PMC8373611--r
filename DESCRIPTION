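Package: pragword
Title: Rational Integration of Information Sources in Early Word Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rational-speech-act model of how young children
    integrate speaker informativeness, common-ground (discourse novelty) and
    graded semantic knowledge when inferring the referent of a novel word,
    together with its lesioned and biased competitor variants. Provides
    age-dependent parameter trajectories (linear and logistic regression
    submodels with object-level random effects), a synthetic generator for
    the three experiment designs the models are evaluated on, fully Bayesian
    estimation via an adaptive Metropolis-within-Gibbs sampler over a
    compiled likelihood, out-of-sample posterior prediction, Monte-Carlo
    marginal likelihoods and Bayes factors, and binned model-versus-data
    evaluation with Pearson correlations and highest density intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
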