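Package: mpmfit
Title: Model-Based Multi-Parameter Mapping for Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood and joint-total-variation regularised
    maximum-a-posteriori estimation of quantitative MR parameter maps
    (proton-density scaling, R1, R2*, magnetisation-transfer saturation)
    from multi-echo variable-flip-angle spoiled gradient echo volumes.
    Parameters are encoded by their log (logit for MT saturation) and
    fitted with a Newton-type optimiser whose positive-definite
    approximate Hessian augments the Gauss-Newton matrix with the
    absolute residual times the absolute Hessian diagonal, giving
    empirically monotone convergence where Gauss-Newton and
    Levenberg-Marquardt can diverge. Includes ESTATICS log-linear and
    non-linear baselines with exact analytic inversion of the TE=0
    intercepts, an IRLS scheme for the joint total variation prior with
    preconditioned conjugate-gradient Newton solves, Laplace-approximation
    uncertainty maps with closed-form log-normal moments, synthetic
    single-voxel and 3-D phantom generators, and NIfTI-1/JSON-sidecar
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
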