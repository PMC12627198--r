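Package: ambiddm
Title: Drift-Diffusion Modelling of Ambiguity Preferences in Intertemporal and Risky Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a drift-diffusion model (DDM) family for intertemporal
    choice under time ambiguity and risky choice under probability ambiguity:
    factorial task-design grids, Wiener first-passage-time likelihoods with a
    choice-only likelihood for preference-switch trials, synthetic-cohort
    generation with known ground truth, the exclusion cascade used for online
    behavioural data, per-participant Bayesian estimation with convergence
    diagnostics, model comparison via PSIS-LOO, Akaike-type model weights,
    pseudo-inclusion Bayes factors and random-effects Bayesian model selection
    (protected exceedance probabilities), and cross-domain individual-difference
    analyses (robust Bayesian correlation, ROPE+HDI decision rule).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
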