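Package: prestim
Title: Pre-Stimulus Oscillatory State Analysis for Single-Trial TMS-EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how the phase and power of ongoing EEG
    oscillations before a transcranial magnetic stimulation (TMS) pulse shape
    the single-trial evoked response. Provides a synthetic epoched-EEG
    generator with known ground truth (narrowband oscillators over a 1/f
    background, stimulus artifact, injectable evoked response with optional
    power and phase interactions), deterministic preprocessing (artifact
    excision with linear interpolation, baseline correction, down-sampling),
    pre-stimulus instantaneous phase estimation by zero-phase band-pass
    filtering with autoregressive forward prediction (PHASTIMATE-style),
    Welch band power with band-specific windows, rectified area-under-curve
    response metrics for stimulated and control windows, and group-level
    statistics including the corrected_effect measure that separates the
    stimulus-evoked contribution from continuation of ongoing dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Electrophysiology, TimeCourse, Software, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
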