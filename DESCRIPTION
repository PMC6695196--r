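Package: alleegrowth
Title: Stochastic Birth-Death Models of Low-Density Cell Population Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting Allee effects in small cell populations from
    replicate growth curves. Implements seven stochastic birth-death models
    (exponential, strong Allee, and extended/weak Allee families, with the
    Allee term acting on birth, death, or both), exact Gillespie simulation,
    moment-closure approximations of the mean and variance, maximum-likelihood
    fitting of per-timepoint summary statistics, profile-likelihood confidence
    intervals, and BIC-based model selection. Includes a truncated master
    equation solver used as a validation oracle and seeded end-to-end
    simulation-study and data-analysis pipelines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
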