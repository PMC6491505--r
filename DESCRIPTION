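Package: precistim
Title: Precision-Weighted Vibrotactile Discrimination and Nonlinear
    Effective Connectivity Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and model-based analysis of a paired vibrotactile
    flutter discrimination study. Synthesizes regular and temporally
    jittered ("noisy") sinusoidal stimuli and their cycle statistics,
    runs interleaved adaptive staircases with analytic equilibrium
    accuracies, simulates precision-weighted ideal observers for
    faster-slower and same-different judgments with signal-detection
    summaries, and provides a four-region nonlinear dynamic causal model
    (DCM) toolchain: balloon-hemodynamic forward simulation, MAP
    estimation with a Laplace free-energy approximation to the model
    evidence, random-effects Bayesian model selection with exceedance
    probabilities, and end-to-end model and parameter recovery on
    synthetic group data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
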