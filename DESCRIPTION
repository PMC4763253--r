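Package: streamscore
Title: Dual-Measure Analysis of Auditory Stream Segregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stimulus scheduling, deviant-detection scoring, and perceptual
    build-up analysis for ABA- triplet streaming experiments that combine
    subjective percept reports with an objective temporal-deviant detection
    task. Implements signal-detection scoring with time-normalized false-alarm
    "trials", proportion-segregated build-up curves, a covert-attention mixture
    model scanned over the per-window attention probability q with
    one-dimensional statistical parametric mapping (random field theory and a
    sign-flip permutation analogue), and a random-intercept logistic model
    ladder fitted by Gauss-Hermite quadrature with the adjusted count
    pseudo-R-squared. A synthetic listener simulator with planted parameters
    drives end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
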