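Package: ssepTrack
Title: Tracking the Time Evolution of Steady-State Evoked Potentials by
    Column-Wise Averaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the time course of steady-state evoked
    potentials (SSVEP, ASSR, SSSEP) from repeated stimulation runs. Epochs
    occupying the same temporal position in independent runs are averaged
    across runs ("column-wise"), never across positions within a run, so the
    averaged waveform preserves the response dynamics (onset integration,
    adaptation, extinction). Includes a synthetic multi-run EEG simulator with
    a known time-varying response envelope, pink/white background noise and
    blink/motion artifacts; zero-phase preprocessing (band-pass, notch,
    resampling, segmentation, detrending, baseline correction); epoch-level
    artifact rejection and inverse-variance weighting; FFT-based extraction of
    response amplitude, residual noise level (RNL) and peak signal-to-noise
    ratio (pSNR); progressive-averaging curves; and EDF/BDF and delimited-text
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
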