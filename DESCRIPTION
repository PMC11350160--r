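Package: lungtdos
Title: Time-Domain Diffuse Optics Toolkit for Transcutaneous Lung Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-domain diffuse optical spectroscopy (TD-DOS) of deep
    tissue, oriented at transcutaneous sensing of the human lung. Implements the
    analytic time-resolved reflectance of a semi-infinite turbid medium under
    extrapolated boundary conditions with instrument-response-function
    convolution; a layered-slab time-resolved Monte Carlo photon-transport
    kernel with microscopic Lambert-Beer trajectory storage, post-hoc absorption
    reweighting, correlated-sampling perturbation contrast and
    maximum-penetration-depth statistics; inverse fitting of photon
    time-of-flight distributions for absorption and reduced scattering;
    broadband chromophore decomposition and power-law scattering analysis; and
    gated-contrast analysis of paced-breathing protocols, together with a
    synthetic-data generator emulating TCSPC acquisition statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    pracma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
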