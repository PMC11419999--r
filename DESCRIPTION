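Package: pacavity
Title: Photoacoustic Imaging Simulation of Cavity-Structure Phantoms and
    Artifact-Removal Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates photoacoustic tomography of tissue-mimicking phantoms
    containing blood, air and water tubes embedded in an agarose substrate.
    Provides phantom construction (horizontal and Latin-square tube layouts),
    optical excitation models (uniform illumination and Monte Carlo photon
    transport for Gaussian beams), k-space pseudospectral acoustic forward
    simulation on heterogeneous media with a half-ring sensor array,
    delay-and-sum image reconstruction, Perona-Malik anisotropic diffusion and
    non-local means artifact removal, and an evaluation suite (PSNR, SSIM, MSE,
    NAE and their lift ratios) including semicircular-artifact isolation and a
    beam-waist uniformity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tiff,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
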