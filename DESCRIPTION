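Package: scFTIR
Title: Single-Cell FTIR Spectral Phenotyping and Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for biochemical phenotyping of single cells from
    mid-infrared absorbance spectra: a parametric band-model simulator of
    two-population single-cell FTIR data (with baseline drift, noise and
    resonant Mie scattering distortion), spectral pretreatment
    (Savitzky-Golay smoothing, rubberband/polynomial baseline correction,
    iterative resonant-Mie extended multiplicative signal correction,
    second derivatives, region extraction, band semi-quantification),
    cell-to-cell Euclidean distance heterogeneity analysis (in-group and
    inter-group distance sets, Gaussian-fitted distance histograms, Ward
    hierarchical clustering), and PCA with 95% confidence-ellipse
    classification scored by sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    signal,
    minpack.lm,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
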