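Package: scattergap
Title: Detector-Gap Inpainting for 2D X-Ray Scattering Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to reconstruct the dead inter-module stripes of tiled
    photon-counting detectors (such as the PILATUS3 2M) in two-dimensional
    small- and wide-angle X-ray scattering images. Provides the gap-mask
    geometry of module-tiled detectors, a parametric synthetic scattering
    image generator (Debye-Scherrer rings, Bragg peaks, diffuse background,
    beamstop shadows), a strip-cropping data augmentation scheme that
    manufactures ground truth for vertical gaps, four trainable
    convolutional inpainting networks (convolutional autoencoder, tunable
    U-Net, partial-convolution U-Net and mixed-scale dense network) built on
    compiled convolution kernels, a biharmonic inpainting baseline,
    overlap-averaged stitched inference, gap-restricted L1/Pearson
    evaluation, and latent-space neighbourhood analysis of inpainting
    quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tiff,
    png,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
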