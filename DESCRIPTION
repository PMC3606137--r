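Package: leakygate
Title: Leaky- and Gated-Integrator Models of Perceptual Task Switching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for evidence-accumulation
    models of perceptual task switching.  A synthetic population of MT
    (middle temporal area) neurons with joint direction and depth tuning
    feeds an eight-neuron readout bank whose differential signals drive a
    family of two-accumulator decision models (gated integrator,
    time-varying gate, single- and double-leaky integrators).  Behavioral
    output is analysed with task-wise logistic models, a wrong-task
    mixture model compared by AIC, switch ratios, and Weibull 75 percent
    thresholds; neural output is analysed with z-scored, ROC-based choice
    probabilities and their time courses, with bootstrap confidence
    intervals.  Includes calibration of the gate weight and the gate time
    constant against a behavioral switch-ratio target and late
    task-commitment simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
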