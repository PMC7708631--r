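Package: gazewalk
Title: Dynamical Scan-Path Models of Scene Viewing with Perisaccadic
    Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, exact likelihood evaluation, and Bayesian
    parameter inference for dynamical models of human scan-path
    generation during scene viewing (the SceneWalk model family).
    Implements the baseline activation/inhibition priority-map dynamics
    and the extended model with pre- and post-saccadic attention shifts,
    facilitation of return, center-bias initialization, and an
    oculomotor potential favouring cardinal saccade directions.
    Includes a differential-evolution MCMC sampler for per-subject
    posterior inference, the gaze statistics used to evaluate such
    models (saccade amplitude and angle distributions, turning-angle
    dependencies, saccade-relative landing densities), a velocity-based
    saccade detector, and synthetic-data generators so the whole
    pipeline runs without external corpora.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
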