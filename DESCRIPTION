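Package: clamploop
Title: Simulated Closed-Loop Cellular Electrophysiology Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale block library for closed-loop cellular
    electrophysiology protocols run against simulated neuronal
    preparations instead of acquisition hardware. Provides a fixed-step
    block-graph execution engine, point-neuron and conductance-based
    neuron models (LIF, QIF, adaptive exponential IF, Hodgkin-Huxley,
    reduced Traub-Miles), Tsodyks-Markram short-term synaptic dynamics
    and a pipette-electrode circuit; Ornstein-Uhlenbeck point-conductance
    synaptic background under the diffusion approximation with optional
    sinusoidal rate modulation; active electrode compensation (kernel
    estimation from a uniform-noise probe, electrode/membrane kernel
    separation and online artifact subtraction); sample-and-hold
    closed-loop controllers (spike-triggered PID firing-rate clamp, gated
    PI voltage hold, response-probability clamp and EPSP-size clamp); and
    offline analyses (cycle histograms and sinusoidal transfer fits, F-I
    curves and gain modulation, interspike-interval statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
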