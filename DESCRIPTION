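Package: pulsebp
Title: Cuffless Blood-Pressure Estimation from PPG and ECG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous cuffless estimation of systolic and diastolic blood
    pressure from synchronized photoplethysmography (PPG) and single-lead ECG.
    Provides wavelet-packet denoising with cubic-spline baseline removal,
    detection of ECG R-peaks and the six classical PPG fiducial points,
    extraction of 22 pulse-waveform characteristics plus body-mass index and
    gender, mean-impact-value (MIV) feature screening, a single-hidden-layer
    feedforward network trained by Levenberg-Marquardt whose initial weights
    are optimized by a multiple-population genetic algorithm (MPGA),
    per-individual model integration via MPGA-fitted proportional
    coefficients, and clinical agreement evaluation (RMSE/MAD/STD, AAMI,
    BHS grading, Pearson correlation, Bland-Altman). A seeded synthetic
    PPG+ECG record generator with planted fiducial truth and a documented
    ground-truth pressure function supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
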