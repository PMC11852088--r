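Package: reacharm
Title: Hierarchical Neuromuscular Reaching Simulation and Human-Aware Robot Assistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates planar human reaching with a hierarchical sensorimotor
    model: a stochastic optimal feedback controller with signal-dependent
    noise and delayed sensory estimation acting on a low-dimensional internal
    model, a muscle-synergy dimension-expansion stage solved by non-negative
    least squares, and a two-link, six-muscle Hill-type musculoskeletal arm.
    The arm can be rigidly coupled to a two-link robot whose torques are
    chosen either by an impedance controller or by a human-aware nonlinear
    model-predictive controller that rolls out the full human model to
    minimize predicted neuromuscular effort. Includes center-out and
    curl-force-field reaching experiments, four interaction scenarios,
    movement metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
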