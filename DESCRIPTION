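Package: msiclass
Title: Diagnostic Classification of MALDI Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building diagnostic classifiers from MALDI mass
    spectrometry imaging (MSI) data. Provides imzML input/output, per-spectrum
    preprocessing (Savitzky-Golay smoothing, TopHat morphological baseline
    subtraction, total-ion-current normalisation), MAD-based signal-to-noise
    peak picking, ppm-tolerance peak alignment with presence filtering,
    patient-level average spectral profiles and peak-list matrices, recursive
    feature elimination scored by a partial least squares classifier under
    repeated cross-validation, radial-kernel support vector machine training
    and grid tuning, external validation with full diagnostic metrics
    (sensitivity, specificity, PPV, NPV, ROC AUC), and pixel-by-pixel
    classification of whole smears rendered as class maps. A synthetic
    MSI cohort generator with known ground truth supports end-to-end
    verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    kernlab,
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
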