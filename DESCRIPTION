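Package: chronocircuit
Title: Neural Circuit Model of Human Sensorimotor Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a modular rate-unit circuit model of human sensorimotor
    timing. Two mutually inhibitory units drive a ramping output toward a
    movement-initiation threshold at a speed set by a shared tonic input. A
    motor planning module resets itself after every threshold crossing to
    produce rhythms; a sensory anticipation module is reset by stimuli and
    adjusts the shared input so that its output reaches threshold at the
    anticipated time of the next event; a phase-correction pathway couples the
    two. The package provides the Euler-integrated dynamics (compiled core),
    stimulus-train generators for tracking, perturbation, reproduction and
    synchronization/continuation protocols, behavioral metrics (asynchrony,
    phase, RMSE, BIAS/VAR decompositions, Rayleigh test), random-search
    parameter-fitting procedures, and a linear error-correction algorithm used
    as a behavioral baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
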