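Package: znppfluor
Title: Non-Invasive Zinc Protoporphyrin Quantitation by Dual-Wavelength
    Fluorescence Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies erythrocyte zinc protoporphyrin (ZnPP), a biomarker
    of functional iron deficiency, from fibre-probe fluorescence emission
    spectra of the oral mucosa. Implements dual-wavelength (425/407 nm)
    excitation difference spectroscopy, second-derivative smoothness
    fitting of ZnPP, protoporphyrin IX and blood-absorption amplitudes,
    blood-absorption-index site qualification, the van Veen vessel-packaging
    absorption correction, a layered Monte Carlo photon-transport simulator
    with weighted direct fluorescence emission, a synthetic spectrum and
    cohort generator, and robust method-comparison statistics (zero-offset
    robust scaling, tau-scale Bland-Altman limits of agreement with
    bootstrap confidence intervals, ROC cutpoint selection and diagnostic
    test metrics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
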