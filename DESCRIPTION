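Package: vnseg
Title: Coupled Variational Networks for Joint Denoising and Segmentation
    of Melanoma Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable variational networks for the joint reconstruction
    (denoising) and segmentation of stained melanoma tissue-section images,
    together with a stochastic generator of histology-like training images
    with exact ground truth. The network unrolls a fixed number of projected
    gradient steps of a coupled image/mask energy with learned convolution
    kernels and Gaussian radial-basis-function nonlinearities, trained with a
    projected Adam optimizer under zero-mean and l1-ball kernel constraints.
    The generator synthesizes immunofluorescence and H&E-like scenes from
    declarative scene scripts (layered ellipse, patch-mosaic and fast-marching
    geometry with multivariate-normal color texture) and derives segmentation
    ground truth from neighborhood concentration rules. Reinhard color-transfer
    normalization for H&E images is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
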