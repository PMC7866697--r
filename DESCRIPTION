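Package: somnoscope
Title: Spectral, Spike, Sleep-Stage and Spindle Analysis of Rodent
    EEG/EMG Telemetry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous rodent electroencephalogram
    (EEG) and electromyogram (EMG) telemetry recordings: Welch power
    spectral density with band powers and total/relative delta summaries,
    amplitude-threshold epileptiform spike counting with movement-artifact
    exclusion, rule-based four-state sleep staging with hypnogram,
    light-dark architecture and 2-h bin metrics, and automated sleep
    spindle detection by cubed-RMS thresholding of a 10-15 Hz band-filtered
    trace.  A synthetic telemetry generator produces recordings with known
    per-second stage schedules, injected spikes and injected 11 Hz spindle
    bursts so that every detector can be validated against ground truth.
    Includes a group-comparison layer (pooled-variance t tests, Holm-Sidak
    step-down adjustment, simple linear regression) and EDF interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
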