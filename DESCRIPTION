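Package: eegqc
Title: Signal-Quality Validation of Wearable Versus Clinical Routine EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for validating the signal quality of a wearable EEG
    device against a clinical reference recording the same routine-EEG
    session (eye open/close, hyperventilation, photic stimulation).
    Implements segmentation and order-5 Butterworth band-pass
    pre-processing, SNR/PSNR/MSE quality metrics under a power-frequency
    noise model, discrete-wavelet-transform clinical band energies with
    device-specific dyadic decomposition depths, stimulus-response indices
    (alpha reactivity, hyperventilation slowing, photic driving), and a
    deterministic synthetic two-device session generator so the whole
    pipeline is testable without clinical recordings. Reads and writes EDF,
    OpenBCI-style CSV, and annotation/report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
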