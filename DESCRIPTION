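Package: astrorf
Title: Receptive-Field Estimation for Astrocyte and Neuron Calcium Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spectrotemporal receptive fields from calcium event
    trains recorded during ultrasonic-vocalization playback. Implements
    stimulus spectrogram preprocessing with PCA reduction, second-order
    Maximum Noise Entropy (MNE) logistic encoding models with shuffle-based
    significance testing, receptive-field feature extraction with modulation
    power spectra, and principal-angle quantification of subspace overlap
    between cell populations (e.g. astrocyte functional units versus
    neurons). A synthetic-data module generates frequency-modulated
    vocalization-like stimuli and event rasters from known ground-truth
    encoding models so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
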