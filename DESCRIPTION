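Package: cogtomo
Title: Cognitive Tomography of Sequence Learning from Response Times
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers individualized dynamical internal models of sequence
    learning from trial-by-trial response times in the Alternating Serial
    Reaction Time (ASRT) task. A participant is modelled as a Bayesian
    filter over a discrete hidden Markov internal model whose next-stimulus
    predictions drive response times through the LATER (linear ascent to
    threshold with ergodic rate) model; the joint posterior over internal
    model and response-time parameters is sampled with a slice-truncated
    No-U-Turn sampler under a truncated hierarchical Dirichlet process
    prior. Includes exact ideal-observer, Markov and trigram reference
    models, an ASRT stimulus generator, a synthetic-participant simulator
    with a parameter-recovery harness, and model-comparison metrics
    (explained variance, Kullback-Leibler divergence, error-trial rank and
    ROC analyses, higher-order learning scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
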