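Package: dopplertrace
Title: Automated Peak Velocity Profile Extraction from Pulsed-Doppler
    Echocardiography Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts positive and negative peak blood-velocity profiles
    (Doppler-shift envelopes) from pulsed-Doppler echocardiography
    spectrogram images by two per-column intensity-thresholding edge
    searches: one scanning from the region-of-interest borders toward the
    zero-velocity baseline, and one scanning from the baseline outward
    anchored to a near-baseline search window. Includes moving-average
    image smoothing, profile averaging, pixel-to-physical axis
    calibration, E/A diastolic wave measurement, Bland-Altman agreement
    analysis, profile spectra, a Canny-style comparison baseline, and a
    synthetic spectrogram generator with known ground-truth envelopes so
    every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
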