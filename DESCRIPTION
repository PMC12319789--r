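Package: rerpsim
Title: Simulation and Regression-Based Overlap Correction for Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate single-channel event-related potential (ERP)
    recordings under competing ground truths (timescale-invariant
    stimulus- and response-locked components, a stimulus-to-response
    accumulation-to-bound ramp, and a diffusion-type evidence-accumulation
    process with jittered non-decision delays), and to analyse them with
    regression-based overlap correction: time-expanded FIR (stick-function)
    design matrices over stimulus and response events, optionally split by
    reaction-time category, fitted jointly by sparse least squares.
    Includes epoching, median reaction-time splits, pre-response amplitude,
    buildup-slope and baseline measurements, component subtraction, and
    orchestrated experiments demonstrating when overlap correction removes
    spurious reaction-time effects and when it removes real ones.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
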