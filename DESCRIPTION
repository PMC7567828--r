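Package: spindler
Title: Wavelet-Based Sleep Spindle Detection and Thalamocortical Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles (9-16 Hz transient oscillations of NREM
    sleep) from EEG/LFP recordings using thresholded continuous-wavelet-transform
    energy with a complex frequency B-spline mother wavelet, after screening a
    set of candidate wavelet families by their normalized spindle power on
    annotated data.  Includes per-event feature extraction (central frequency,
    cycles, peak-to-peak amplitude, symmetry), vigilance-state-resolved spindle
    rate dynamics around NREM-to-REM and NREM-to-wake transitions, single-unit
    spike and burst detection, spike-field and slow-wave/spindle coupling,
    UP-state detection and coincidence, and a synthetic polysomnography
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
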