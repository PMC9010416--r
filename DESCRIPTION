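Package: wrinklefm
Title: Wrinkle Force Microscopy Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for wrinkle force microscopy (WFM): quantifying the
    contractile forces of adherent cells from the wrinkles they induce in a
    stiff-skinned elastic substrate. Implements forward and inverse traction
    force microscopy on an elastic half-space (Boussinesq Green's function,
    Fourier-transform traction cytometry with Tikhonov regularization and
    L-curve parameter selection, block-matching particle image velocimetry),
    wrinkle geometry and traction statistics (skeleton length, FFT principal
    direction, contractile stress tensor, isotropy), thin-film buckling
    mechanics of the bilayer substrate (wavelength, amplitude, critical
    strain, stiffness-ratio inversion), a synthetic contractile-cell
    generator producing physically consistent image/traction pairs, the
    arctangent force-to-grayscale codec with weighted magnitude/angle error
    metrics, and a conditional image-to-image translator (U-Net generator
    with patch discriminator, pix2pix objective) that predicts traction
    fields directly from images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
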