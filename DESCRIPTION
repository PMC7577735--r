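Package: crossloop
Title: Closed-Loop System Identification of Visuomotor Tracking and
    Acceleration-Dependent Feedback for Dysmetria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for frequency-domain system identification of human
    visuomotor tracking behaviour and for adaptive tuning of altered visual
    feedback in single-joint reaching.  Implements sum-of-sines stimulus
    design with prime-multiple frequencies, phasor (frequency-response)
    estimation from tracking trials, delayed McRuer crossover-model fitting
    with leave-one-out structure selection and bootstrap confidence
    intervals, Smith-predictor equivalence checks, and an
    acceleration-dependent cursor transformation with a PEST adaptive
    staircase for reducing reach dysmetria.  Includes closed-loop subject
    simulators (delayed scaled-integrator trackers and mismatched-inertia
    reachers) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
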