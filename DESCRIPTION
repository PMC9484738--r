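Package: stpe
Title: Short-Time Ultrasound Poroelastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimation of Young's modulus, Poisson's ratio and vascular
    permeability of an inclusion ("tumor") embedded in a softer background
    from time series of axial and lateral strain images acquired under
    sustained (creep) compression. Implements an analytic forward model
    (Eshelby interior strains with first-order exponential creep relaxation),
    a convolution-model ultrasound radio-frequency simulator, two-step
    dynamic-programming plus Horn-Schunck speckle tracking, variable
    projection exponential fitting with empirical-orthogonal-function
    denoising, Eshelby cost-function inversion of the elastic moduli, and
    conversion of the fitted strain time constant into vascular permeability.
    Includes an evaluation harness that quantifies the estimation error as
    the temporal window of observation is shortened to multiples of the
    underlying strain time constant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
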