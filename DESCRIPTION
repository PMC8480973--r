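Package: delaystand
Title: Delayed-Feedback Standing Balance: Simulation and Vestibulomotor Analysis
Version: 0.1.0
Authors@R: person("delaystand", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulates standing balance as a linearized inverted pendulum under
    delayed ankle-torque feedback with virtual angular limits, and implements the
    accompanying analysis toolchain: windowed sway-velocity variance and
    exponential learning-curve fits, segment-averaged Fourier estimates of
    vestibular-stimulus-to-EMG coupling (coherence, gain, cross-covariance with
    confidence rules and biphasic peak extraction), Morlet-wavelet time-frequency
    coupling around delay transitions, and Bayesian lapse-mixture psychometric
    fitting of unexpected-motion detection. A synthetic-data generator emulates
    the stimuli, EMG envelopes, button responses and session designs so the whole
    pipeline is testable without human or robot data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
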