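Package: spherosim
Title: Hybrid Discrete-Continuous Simulation of Drug-Treated Glioblastoma Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic hybrid discrete-continuous (HDC) simulator of
    glioblastoma spheroid growth under chemotherapy. Lattice cell agents with
    stochastic cycling, space-limited quiescence and lysis are coupled to
    continuous drug concentration fields governed by reaction-diffusion
    transport with Dirichlet bath boundaries and scheduled medium exchanges.
    In vitro dose-response curves are converted into per-cell, per-cycle fate
    probabilities spanning cytostatic and cytotoxic mechanisms; combination
    therapy is simulated under a probabilistic-independence null model with
    Bliss-style supra-additivity scoring, together with growth-inhibition,
    IC50 and RMSE evaluation metrics and synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
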