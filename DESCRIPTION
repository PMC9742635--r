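Package: mlnmr
Title: Multilevel Network Meta-Regression for Ordered Categorical Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-adjusted indirect treatment comparison on evidence
    networks that mix individual patient data (IPD) and aggregate data (AgD)
    studies, for ordered categorical outcomes such as PASI 75/90/100 response.
    Fits multilevel network meta-regression models with an ordered probit (or
    logit) likelihood: the individual-level regression is averaged over each
    aggregate study's covariate joint distribution, reconstructed from
    published marginal summaries via a Gaussian copula and quasi-Monte Carlo
    integration. Supports fixed- and random-effects treatment contrasts,
    unrelated-mean-effects inconsistency models, class-shared ("shared effect
    modifier") or treatment-specific interaction structures, model criticism
    via residual deviance, pD and DIC, and population-average estimates
    (conditional and marginal treatment effects, event probabilities) in
    arbitrary target populations including external populations anchored on a
    Beta-distributed baseline risk. Includes a synthetic-data generator for
    psoriasis-like networks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
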