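Package: oisbold
Title: Forward Modelling of Positive and Negative BOLD from Optical Imaging Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis chain linking two-dimensional optical
    imaging spectroscopy (2D-OIS) of cortical haemodynamics to predicted
    gradient-echo BOLD fMRI signals at high field. Includes a synthetic-data
    generator for trial-locked positive and negative haemodynamic responses,
    Monte Carlo photon transport through layered cortical tissue with
    path-length lookup tables, the iterative path-length scaling algorithm
    (PLSA) for Beer-Lambert inversion of four-wavelength attenuation stacks
    into oxy-/deoxy-/total-haemoglobin maps, Monte Carlo simulation of
    extravascular MR signal attenuation around vessel cylinders, general
    linear model activation mapping with cluster thresholding, and spatial
    concordance tooling (Gaussian smoothing, cubic resampling, affine
    template correlation, projective warping from fiducial points).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
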