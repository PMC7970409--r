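Package: XLCTsynth
Title: Few-View Sinogram Synthesis and Reconstruction for X-Ray
    Luminescence Computed Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for pencil-beam x-ray
    luminescence computed tomography (XLCT). Provides a digital cylindrical
    phantom generator with randomized spherical nanophosphor targets, a
    physics-based scan simulator (Beer-Lambert pencil-beam excitation,
    luminescence source formation, diffusion-approximation Green's-function
    light propagation to fiber-bundle detectors), a residual convolutional
    network that synthesizes full-view (30 projection) sinograms from
    few-view (15 projection) measurements, total-variation regularized
    iterative reconstruction of the nanophosphor concentration map, and
    PSNR/SSIM evaluation, together with a config-driven pipeline for
    dataset generation, training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
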