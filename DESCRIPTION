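Package: okrephys
Title: Purkinje-Cell Intrinsic Excitability and Optokinetic Reflex Gain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for cerebellar oculomotor-learning
    electrophysiology. Extracts intrinsic-excitability measures from whole-cell
    current-clamp step protocols (F-I curves, rheobase, action-potential
    threshold, amplitude and afterhyperpolarization, input resistance, and a
    regular-spiking inclusion label), computes optokinetic-response (OKR) gain
    from screen and eye position traces by desaccading and sinusoid fitting,
    and runs the group comparisons (paired and Welch t-tests, linear mixed
    model with per-step contrasts across the F-I curve). Ships a ground-truthed
    synthetic-data generator built on the adaptive exponential
    integrate-and-fire (AdEx) neuron model, with a closed-form rheobase oracle,
    so every stage of the pipeline can be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    emmeans,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
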