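Package: poldecon
Title: Spatio-Angular Deconvolution for Polarized Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modeling and statistical image reconstruction for polarized
    fluorescence microscopy. Models the vectorial dipole point spread function of
    wide-field, light-sheet (SPIM) and dual-view light-sheet (diSPIM) microscopes,
    simulates polarization-modulated acquisitions of spatio-angular phantoms, and
    reconstructs joint 3D density and orientation (orientation distribution
    function) maps with the efficient generalized Richardson-Lucy (eGRL)
    algorithm, together with baseline solvers (sampled-orientation GRL, the
    pixelwise eGRL-p ablation, scalar Richardson-Lucy, and a per-frequency
    Tikhonov/SVD pseudoinverse). Includes real spherical-harmonic machinery
    (Gaunt coefficients, real Wigner rotations, per-voxel spectral products and
    divisions), ODF-derived analysis maps (density, peak and principal
    orientation, generalized fractional anisotropy, order parameter), image
    quality metrics, and a chunked reconstruct-and-blend pipeline for large
    volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    pracma,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
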