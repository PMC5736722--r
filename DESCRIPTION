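Package: arni
Title: Model-Free Inference of Direct Network Interactions from Nonlinear Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs direct pairwise and higher-order (hypernetwork)
    interactions in network dynamical systems from multivariate time series
    alone, without assuming a dynamical model.  Implements greedy block
    orthogonal least squares over basis-function expansions of the coupling
    terms (the ARNI algorithm), learning-curve (knee) diagnostics, synthetic
    generators for gene-regulatory, phase-oscillator, chaotic and biological
    oscillator benchmark systems, model-free baselines (correlation, partial
    correlation, transfer entropy), and ROC-AUC evaluation against ground
    truth, with tidy tabular outputs and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
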