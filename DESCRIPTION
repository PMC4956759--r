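Package: cartFTIR
Title: FTIR Microspectroscopic Imaging Analysis of Osteoarthritic Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric analysis of Fourier transform infrared (FTIR)
    microspectroscopic images of articular cartilage. Provides a hyperspectral
    cube container with quality masks, synthetic layered-cartilage phantom
    generation with grade-dependent proteoglycan depletion and collagen-network
    degradation, spectral preprocessing (quality filtering, extended
    multiplicative signal correction, vector normalization, Savitzky-Golay
    second derivatives), PCA-based bone segmentation with normalized depth
    mapping, univariate spectral parameters (amide I and carbohydrate areas,
    collagen integrity, second-derivative peaks), K-means cluster imaging on
    combined multi-sample matrices, and prediction of histopathological
    osteoarthritis grade by partial least squares regression with competitive
    adaptive reweighted sampling (CARS) variable selection under leave-one-out
    cross-validation, together with cohort-level rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    withr,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
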