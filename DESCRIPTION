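Package: ebwdenoise
Title: Entropy-Based Wavelet Denoising of Charge-Detection Ion-Trap Mass
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Removes strong swept radio-frequency (RF) and auxiliary
    alternating-current (AC) interference from frequency-scan transients
    recorded by charge-sensing detectors in linear ion trap mass
    spectrometry. Implements multilevel discrete wavelet decomposition with
    periodized padding over a catalogue of 105 standard wavelets,
    energy-to-Shannon-entropy-ratio (ESER) mother-wavelet selection,
    median-based per-level universal thresholding with hard or soft rules,
    morphological (top-hat) baseline correction, and signal-to-noise
    improvement reporting. Includes a synthetic transient simulator with
    phase-continuous chirped interference for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
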