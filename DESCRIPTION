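Package: probeacc
Title: Accumulator Models and Metacognitive Reporting in Probe Paradigms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for probe-paradigm studies of
    self-initiated action. Implements four generative models of action
    initiation (classic readiness-potential onset, leaky stochastic
    accumulation, linear ballistic accumulation, and a pink-noise-input
    accumulator), probe scheduling with trial-outcome categorization,
    single-stage, dual-stage, and random metacognitive reporting models,
    event-locked epoching with back-averaging and pre-event statistics,
    a multi-participant synthetic EEG generator with known ground truth,
    complex Morlet wavelet time-frequency decomposition with band power
    extraction, and trial-level hierarchical (mixed-effects) inference
    with corrected post hoc contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
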