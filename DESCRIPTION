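Package: radarbp
Title: Cardiac Timing and Blood Pressure Estimation from Quadrature Doppler Radar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Non-contact estimation of per-beat cardiac timing (systolic and
    diastolic durations, interbeat interval) and cuffless blood pressure from
    continuous-wave Doppler radar I/Q recordings. The chest signal is band-pass
    filtered to the 8-30 Hz vibration band, converted to a spectrogram by
    short-time Fourier transform, and summed over 5-30 Hz into an integrated
    spectrum whose per-beat peak pairs mark systole and diastole onsets. Two
    segmenters recover the cardiac phases from that waveform: a four-state
    duration-dependent hidden semi-Markov model with logistic-regression
    emissions and an extended Viterbi decoder, and a 1D U-net trained on
    ECG-derived phase labels. Per-segment timing features feed a random-forest
    regressor for systolic and diastolic blood pressure under subject-grouped
    cross-validation. A physics-based simulator generates synthetic radar,
    ECG and blood-pressure cohorts with full ground truth for end-to-end
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    nnet,
    ranger,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
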