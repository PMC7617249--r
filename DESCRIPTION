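Package: mmreg
Title: Multimodal Nonlinear Image Registration with Cubic B-Spline Warps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Small-deformation nonlinear registration of 3D scalar and
    diffusion-tensor volumes. The deformation is parametrised by cubic
    B-splines and estimated by sparse Gauss-Newton / Levenberg-Marquardt
    optimisation of a mean-squared-error scalar cost and a mean-squared
    Frobenius-norm tensor cost with finite-strain reorientation of the
    reference tensors, regularised by the mean squared log of the local
    Jacobian singular values so that accepted warps stay diffeomorphic.
    Includes an optional multiplicative bias-field model on the reference
    image, a Nyquist-safe multiresolution pyramid, inverse-consistency
    weighting, an evaluation-metric suite (Jaccard index, modified
    Hausdorff distance, tensor overlap and shape-weighted eigenvector
    similarity, Jacobian-based distortion measures), and a deterministic
    synthetic phantom generator with known ground-truth warps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
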