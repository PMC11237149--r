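Package: aquaphot
Title: Aquaphotomics and NIR Chemometrics for Biofluid Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for near-infrared (NIR) diagnostic
    classification of water-dominated biofluid spectra (blood plasma,
    saliva) with an aquaphotomics layer.  Provides spectral pretreatment
    operators (SNV, MSC, Savitzky-Golay smoothing and derivatives,
    detrending, baseline correction, normalisation), PCA with Hotelling
    T2 outlier screening, PCA-LDA, PCA-QDA and soft-margin SVM
    classifiers, leave-one-out and calibration/test-split validation
    with confusion-matrix quality metrics, the twelve water matrix
    coordinate (WAMAC) absorbance bands of the 1300-1600 nm first
    overtone region, aquagram computation, and a seeded synthetic cohort
    generator emulating class-dependent water-band perturbations so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    e1071,
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
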