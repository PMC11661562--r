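Package: survforestbench
Title: Benchmarking Framework for Survival Forest Methods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-based benchmarking of forest ensembles for
    right-censored time-to-event data. Provides synthetic data-generating
    mechanisms (Weibull proportional hazards, lognormal accelerated failure
    time, and generalized gamma responses with crossing hazards over a mixed
    covariate design), signal-to-noise and censoring-rate calibration, a
    survival-forest engine covering log-rank and related splitting criteria,
    recursively imputed survival trees, rotation forests and conditional
    inference forests, the absolute-loss, concordance-error and integrated
    Brier score metrics, and a factorial experiment runner producing
    relative-mean summaries and tidy exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
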