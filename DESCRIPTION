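Package: itdsense
Title: Interaural Time Difference Sensitivity Analysis for Binaural
    Cochlear-Implant Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify behavioral and neural sensitivity to
    interaural time differences (ITDs) in two-alternative forced-choice
    lateralization experiments with bilateral cochlear implants or
    acoustic click stimulation.  Builds sample-quantized binaural pulse
    and click trains, simulates 2AFC sessions with correction-trial
    dynamics, fits a four-parameter cumulative-Gaussian psychometric
    model (sensitivity, ear bias, lapse rate, spout bias) by maximum
    likelihood with slope and 75 percent-correct threshold estimators and
    Wilson score intervals, and quantifies multi-unit ITD tuning from
    extracellular recordings via analog multi-unit activity (AMUA)
    extraction, threshold-crossing spike detection, normalized tuning
    curves and the signal-to-total variance ratio (STVR) with one-way
    ANOVA significance.  Synthetic-data generators for both behavior and
    recordings make every stage testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
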