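# mpmfit

Model-based multi-parameter mapping for quantitative MRI: direct
maximum-likelihood (SPGR-ML) and joint-total-variation regularised
maximum-a-posteriori (SPGR+JTV) estimation of **A** (proton-density
scaling), **R1**, **R2\*** and **MTsat** from multi-echo,
variable-flip-angle spoiled gradient echo volumes.

The package is for researchers processing MPM-style acquisitions (or
simulating them) who want model-based maps with per-voxel uncertainty,
and for methods work on the optimisation itself.

## The model

Every echo volume is a noisy observation of the SPGR steady state

```
s = A sin(α) (1−δ)(1−e^{−R1·TR}) / (1 − (1−δ) cos(α) e^{−R1·TR}) · e^{−R2*·TE}
```

with δ = 0 for non-MT contrasts. Parameters are log-encoded
(A = e^ã, R1 = e^r̃1, R2\* = e^r̃2, δ = sigmoid(δ̃)) and fitted by
Newton iterations using the *residual-loaded approximate Hessian*

```
P̃ = Σᵢ (1/σᵢ²) [ gᵢgᵢᵀ + |sᵢ − xᵢ| · |diag Hᵢ| ]
```

— the Gauss-Newton matrix plus the absolute residual times the absolute
signal-Hessian diagonal. On the exponential-type objectives of
relaxometry this keeps every step inside the monotone region where
plain Gauss-Newton and Levenberg-Marquardt overshoot or diverge. The
MAP mode adds a joint total variation prior over the four maps (edges
shared across channels), optimised by IRLS with closed-form weight
updates and preconditioned conjugate-gradient Newton solves. ESTATICS
baselines (log-linear and non-linear joint R2\* fits with exact
analytic intercept inversion) and Laplace-approximation uncertainty
maps are included.

## Worked example

```r
library(mpmfit)

# a 32^3 synthetic MPM session: 3 contrasts (21/6/6 deg, one MT),
# 8/8/6 echoes, TR 25 ms, Gaussian noise sigma = 3
ph  <- make_phantom(dim = c(32, 32, 32), sigma = 3, seed = 1)

fit_ml  <- mpm_fit(ph$series, mode = "ml")
fit_map <- mpm_fit(ph$series, mode = "map", lambda = 10)

rmse <- function(fit, k) sqrt(mean((fit$maps[,,,k] - ph$truth[,,,k])^2))
round(rbind(ml  = sapply(1:4, rmse, fit = fit_ml),
            map = sapply(1:4, rmse, fit = fit_map)), 4)
#>       [,1]   [,2]   [,3]  [,4]
#> ml  0.0357 0.0528 3.9091 0.224
#> map 0.0239 0.0345 0.5789 0.093
```

The columns are the per-map RMSEs of the fitted log-encoded maps
(ã, r̃1, r̃2, δ̃) against the ground truth: the JTV prior reduces the
error on every map, most dramatically for r̃2 in the low-R2\* region
where a 16 ms echo train carries little decay information. Natural-unit
maps come from `parameter_maps(fit_map)`; per-voxel posterior standard
deviations and expected R1/T1 maps from `uncertainty_maps(fit_map)`.

Real data enter through `read_series("dir/")` (NIfTI volumes with BIDS
style JSON sidecars: `FlipAngle` in degrees, `RepetitionTime` and
`EchoTime` in seconds, `MTState`); results leave through
`write_maps(fit, "out/")`. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/qmap.R simulate --kind phantom --out sim/
Rscript inst/cli/qmap.R fit sim/ --mode map --lambda 10 --out maps/
Rscript inst/cli/qmap.R benchmark --n-voxels 200 --iterations 1000 --out bench/
```

See `vignette("mpmfit-methods")` for the model, the monotone-step
analysis behind the approximate Hessian, and every tunable default.

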