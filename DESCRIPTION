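Package: darklung
Title: Grating-Based X-Ray Dark-Field Analysis of Pulmonary Emphysema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for grating-based X-ray
    dark-field projection imaging of pulmonary emphysema. Generates
    phase-stepping phantom acquisitions of healthy and emphysematous
    lungs, retrieves transmission, differential-phase and dark-field
    maps by Fourier analysis of the stepping curves, segments lung
    tissue on the dark-field channel, computes the thickness-invariant
    normalized-scatter statistic S = -ln(V)/(ln(T) - c), compares
    groups with Mann-Whitney tests and per-pixel/per-individual ROC
    analysis including paired DeLong AUC comparison, and renders
    IQR-normalized color-coded parametric emphysema maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
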