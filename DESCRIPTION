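Package: digp
Title: Physics-Guided Genetic Programming for Diffuse Optical Image Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs two-dimensional absorption anomalies hidden inside
    strongly scattering slabs from transmitted-light camera measurements using
    tree-based genetic programming guided by a diffusion-equation forward model.
    Provides the continuous-wave diffusion Green's function and Born-approximation
    sensitivity matrix for a slab geometry, a synthetic phantom and measurement
    generator with SNR-threshold masking, a Koza-style genetic-programming engine
    with a sliding-window patch-to-pixel reconstruction operator, a composite
    physics-informed/MSE/Dice fitness, a conjugate-gradient analytical baseline,
    and MSE/SSIM/PCC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    png,
    tiff,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
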