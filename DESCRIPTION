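Package: bsmecg
Title: Beat Score Map Images for ECG Rhythm Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies cardiac rhythms (normal sinus rhythm, atrial
    fibrillation, atrial flutter, supraventricular tachyarrhythmia,
    ventricular bigeminy and trigeminy, sinus bradycardia, paced rhythm)
    from single-lead ECG by converting each 10-second window into a beat
    score map (BSM) image: per-beat classification score vectors are placed
    as columns at their R-peak positions with zeros in between, so the image
    encodes both the sequence of beat types and the R-R interval structure,
    and a compact 2-D convolutional network classifies the images. Includes
    wavelet-based denoising (Daubechies-4), continuous wavelet transform
    scalograms for the per-beat classifier, a labelled synthetic ECG
    generator with calibrated noise injection, imbalance-aware weighted
    sampling, stratified k-fold cross-validation, per-class metric
    reporting, WFDB and plain-text record input/output, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
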