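Package: sfdiops
Title: Optical Property Estimation for Spatial Frequency Domain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and inversion of diffuse reflectance for
    two-frequency spatial frequency domain imaging (SFDI) of turbid media.
    Provides a white Monte-Carlo photon transport kernel for semi-infinite
    homogeneous media with Fresnel boundaries, a closed-form diffusion
    approximation, three-phase demodulation and reference-phantom
    calibration of structured-illumination image stacks, and four inversion
    back-ends mapping calibrated reflectance at spatial frequencies 0 and
    0.2 per mm back to absorption and reduced scattering coefficients:
    dense and low-resolution Monte-Carlo lookup tables, diffusion-model
    root finding, and a random-forest regressor trained on simulated data.
    Includes a synthetic scene generator for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
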