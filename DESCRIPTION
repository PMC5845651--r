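Package: accumtowers
Title: Simulation and Behavioral Analysis of a Pulse-Based Evidence-Accumulation T-Maze Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analyzing the accumulating-towers task,
    a virtual-reality T-maze in which head-fixed mice count brief visual
    pulses (towers) on either side of a 200-cm cue region and turn toward
    the side with more. The package generates the full task protocol
    (spatial-Poisson tower draws with a per-side refractory period,
    adaptive side debiasing, warm-up and easy-block shaping rules, and the
    view-angle controller), provides synthetic behavioral agents with
    known ground truth, and implements the complete analysis stack:
    psychometric curves with lapse rates and surrogate block-selection
    tests, spatial-bin logistic regression of choice on evidence with
    weight-decay inference, history-modulated choice models, a pulse-based
    drift-diffusion accumulator with sensory adaptation fit by exact
    likelihood propagation, signal-detection counting models with scalar
    variability, alternative tower-sampling strategy models, cross-validated
    model comparison in bits/trial, and trajectory/view-angle analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
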