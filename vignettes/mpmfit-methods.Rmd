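---
title: "Model-based multi-parameter mapping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based multi-parameter mapping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmfit)
```

## The estimation problem

Multi-parameter mapping (MPM) protocols acquire multi-echo spoiled
gradient echo (SPGR) volumes at several flip angles, one of them with an
off-resonance magnetisation-transfer pulse. Four tissue parameters govern
the steady-state magnitude signal: a proton-density scaling $A$ (which
absorbs the receive-coil sensitivity), the longitudinal relaxation rate
$R_1$, the apparent transverse relaxation rate $R_2^*$, and the
magnetisation-transfer saturation $\delta$. The forward model is

$$
s(A, R_1, R_2^*, \delta \mid \alpha, TR, TE) =
A \sin\alpha\,
\frac{(1-\delta)\bigl(1 - e^{-R_1 TR}\bigr)}
     {1 - (1-\delta)\cos\alpha\, e^{-R_1 TR}}\,
e^{-R_2^* TE},
$$

with $\delta = 0$ for volumes acquired without the MT pulse. The MT pulse
is modelled as an instantaneous extra saturation (its own repetition time
taken as exactly zero), so a single $\delta$ parameter captures the
additional signal loss.

`mpmfit` fits all four parameters *directly* to every echo of every
contrast by penalised least squares, instead of the conventional two-step
route (per-contrast TE = 0 extrapolation followed by an algebraic
inversion). The noise is modelled as Gaussian — the high-SNR limit of the
Rician magnitude distribution — so the negative log-likelihood is a
non-linear least-squares objective, each volume weighted by the inverse
of its estimated noise variance.

### Log encoding

Each parameter is encoded on the whole real line:
$A = e^{\tilde a}$, $R_1 = e^{\tilde r_1}$, $R_2^* = e^{\tilde r_2}$,
$\delta = \mathrm{sigmoid}(\tilde\delta)$. This makes the optimisation
unconstrained, makes the spatial gradients of the maps invariant to the
choice of unit (seconds vs milliseconds, rates vs times), and improves
the quality of the Gaussian (Laplace) posterior approximation. The
package can also optimise in the *rate* basis $(A, R_1, R_2^*, \delta)$
or the *time* basis $(A, T_1, T_2^*, \delta)$ for comparison; both are
measurably slower to converge (see `benchmark_convergence()`), which is
itself one of the reasons for the log encoding.

## The approximate Hessian

Gauss-Newton (Fisher scoring) drops the residual-curvature term of the
true Hessian to obtain a positive semi-definite surrogate. On exponential
models this surrogate grossly underestimates the curvature on the flat,
non-convex side of the objective, producing steps that overshoot by
orders of magnitude — the classical failure mode of unregularised
non-linear relaxometry fits. The package's optimiser instead keeps the
residual term but takes absolute values of its diagonal:

$$
\tilde P \;=\; \sum_i \frac{1}{\sigma_i^2}\Bigl[
  g_i g_i^{\mathsf T} \;+\; |s_i - x_i|\,\bigl|\mathrm{diag}\,H_i\bigr|
\Bigr],
$$

where $g_i$ and $H_i$ are the gradient and Hessian of the signal for
volume $i$. A one-dimensional analysis motivates this: a positive
preconditioner $h$ yields a monotone step at $y$ whenever
$|g(y)|/h(y) \le |y - y^*|$, i.e. the update lands between the current
point and the optimum. `check_step_condition()` evaluates this
diagnostic on a grid; on the exponential and nested-exponential toy
problems (`toy_problem()`) the condition holds everywhere for $\tilde P$
and fails for Gauss-Newton. No proof is offered for the multivariate
case, and the test suite shows the 1-D guarantee does not carry over
verbatim: on the randomised single-voxel benchmark (log-uniform
acquisition parameters over ten orders of magnitude) a small fraction
of voxels exhibits occasional transient objective increases — of order
0.1% of iterations, self-correcting, and never affecting which method
wins on final likelihood. This is why the full-volume solver safeguards
each Newton step (below); `fit_voxel(method = "proposed")` deliberately
accepts every step so that the raw behaviour of the preconditioner is
observable.

A second variant loads the diagonal with row sums of the absolute
Hessian, $\mathrm{diag}(|H_i|\mathbf 1)$, which provably majorises the
true Hessian. It is more conservative (slower), and is used
automatically for the rate and time bases, which need it for stability;
the mixed second derivatives it requires were derived symbolically and
are finite-difference-tested.

### Baselines

For benchmarking, `fit_voxel()` also implements Gauss-Newton with a
backtracking line search and Levenberg-Marquardt. Both keep one
persistent control factor per voxel, divided/multiplied by 10 on
success/failure, and only accept improving steps. Two bookkeeping
details are not pinned down by the factor-10 schedule itself and were
fixed once here: at most 20 backtracks per iteration (then a zero step), and the
Armijo factor is capped at 1 on success — an Armijo factor scales a
descent direction, so letting it grow past 1 would make the first trial
of every subsequent iteration a guaranteed failure.

## The joint total variation prior

With several maps of the same anatomy, edges co-locate across channels.
The joint total variation (JTV) penalty pools the squared finite
differences of all $K$ maps under one square root per voxel,

$$
\mathrm{JTV}(Y) = \sum_n \Bigl(\sum_k \lambda_k \|G_n y_k\|^2\Bigr)^{1/2},
$$

so sparsity of the spatial gradients is shared across channels: an edge
that exists in one map is cheap to reproduce in the others. $G_n$
extracts all six forward and backward finite differences (divided by the
voxel size in mm, so $\lambda$ keeps one physical meaning across
resolutions). The non-smooth square root is handled by iteratively
reweighted least squares: per-voxel weights
$w_n = (\sum_k \lambda_k\|G_n y_k\|^2)^{-1/2}$ give a quadratic upper
bound that is tight at the current maps, and which the Newton solver can
treat as a Tikhonov term $\tfrac12 y^{\mathsf T} L y$ with
$L = \lambda_k G^{\mathsf T} W G$.

Numerical choices:

* **Boundary rule.** Differences across the volume boundary are zero
  (replicate-edge/Neumann), so constant maps lie in the null space of
  $L$ — the conventional TV choice. The alternative (zero padding) would
  penalise the boundary itself.
* **Flat-region guard.** The weight update divides by the pooled
  gradient magnitude; on exactly flat voxels the argument is clamped at
  $10^{-10}$ times the median nonzero value. Only exactly-flat voxels
  are affected.
* **Default $\lambda$.** A single shared factor of 10 for all four maps,
  the value reported to minimise cross-validated prediction error on
  0.8 mm in-vivo MPM data. Because that calibration depends on
  the gradient scaling (voxel size in mm here), the default is a
  starting point, not a claim of optimality; it is exposed everywhere
  (`lambda` argument, `--lambda` flag).

## The full-volume solver

`mpm_fit()` alternates (MAP mode) IRLS weight updates with inner Newton
steps on the quadratic surrogate. Each Newton system
$(H + L)\,\Delta = g + Ly$ couples voxels only through $L$, and is
solved by preconditioned conjugate gradient with the block-Jacobi
preconditioner $H + \mathrm{diag}(L)$ — the per-voxel $4\times4$
approximate Hessian blocks plus the exact diagonal of the regulariser
(obtained by convolving the weight map with a small cross-shaped
kernel). The default schedule is 10 IRLS iterations,
5 Newton iterations each, 32 CG iterations per Newton step, with
early-stopping tolerances $10^{-5}$, $10^{-5}$ and $10^{-3}$
respectively. In ML mode ($\lambda = 0$) the system is block-diagonal
and solved exactly per voxel; the default caps are 100 iterations at a
$10^{-9}$ relative-gain tolerance, which reaches machine-precision
recovery on noiseless data in well under the cap.

Although the residual-loaded Hessian is empirically monotone, each
Newton step is accepted only if the (surrogate) objective does not
increase; otherwise the step is halved up to 5 times and the event
counted (`fit$halvings`). Noise variances are estimated once per volume
by a two-class Rician mixture EM (background = lowest-mean class),
combined across echoes by the geometric mean, and then held fixed.
Initial maps are spatially constant: $\tilde a$ from the mean
foreground intensity of the lowest-flip non-MT series, and
physiological defaults $R_1 = 1\,\mathrm{s}^{-1}$,
$R_2^* = 20\,\mathrm{s}^{-1}$, $\delta = 0.01$ — only the intensity
scale is data-dependent, and the fit is insensitive to these values.

When acquisition grids differ from the reconstruction grid (inter-scan
motion), maps are *pulled* to each acquisition space by trilinear
interpolation, the likelihood terms computed there, and *pushed* back by
the exact adjoint; the pushed per-voxel blocks majorise the full
resliced Hessian, so the block-diagonal structure is preserved. The
transmit field (B1+) can be supplied as a per-voxel flip-angle scale
(default: ideal). Scaling the likelihood's flip angles this way is one
of several possible conventions, so the field is an optional input
rather than an assumption.

The same solver fits the ESTATICS reparameterisation (one log-intercept
per contrast plus a shared $\log R_2^*$) via `model = "estatics"`; the
regularised variant of the non-linear ESTATICS baseline is exactly this
solver with that likelihood.

## ESTATICS baselines

`loglin_fit()` solves the log-domain least squares
$\log x_{c,e} \approx b_c - R_2^* te$ in closed form; iterative
majorised-Hessian schemes for the same problem reach the same optimum,
so the closed form replaces any iteration schedule. Log-domain residuals
are unweighted. Intensities
are clamped at $10^{-6}$ of the maximum before the log, since magnitude
data can contain zeros. `nonlin_fit()` minimises the intensity-domain
objective with the residual-loaded preconditioner — the loading is what
makes the unregularised non-linear fit stable at all.

With a common TR, the TE = 0 intercepts invert exactly: writing
$y_c = S_c/\sin\alpha_c$ and $x_c = S_c/\tan\alpha_c$, the signal
equation becomes the line $y = A(1-E) + E x$ with $E = e^{-R_1 TR}$,
giving $E$, $A$, $R_1$ in closed form from the two non-MT contrasts and
then $\delta$ from the MT intercept
($1-\delta = S_{MT}/(A\sin\alpha(1-E) + S_{MT}\cos\alpha E)$). The
$\delta$ expression was re-derived from the TE = 0 signal equation and
is validated by exact round-trips rather than against any published
symbol-for-symbol form. Voxels with $E \notin (0,1)$ (noise-dominated)
are flagged `NaN` and counted.

## Uncertainty

At the optimum, the Laplace approximation takes the inverse Hessian as
the posterior covariance of the log-parameters; for tractability the
block-diagonal preconditioner $H + \mathrm{diag}(L)$ is inverted per
voxel instead (`laplace_variance()`). Since the log-parameters are
Gaussian, the parameters themselves are log-normal, and
`lognormal_moments()` returns their closed-form means and variances.
Two conventions are exposed: the standard log-normal mean
$e^{\sigma^2/2} e^{\mu}$ (default, validated against $10^6$-sample
Monte-Carlo), and an `"published"` variant with a full $e^{\sigma^2}$
factor as printed in some of the literature, under which
$E[R_1]\,E[T_1] = e^{2\sigma^2}$ exactly. The variance formula is
identical in both. The discrepancy is documented rather than silently
resolved; the Monte-Carlo oracle in the test suite identifies the
standard form as the mathematically correct one.

These posterior maps capture aleatory uncertainty only: the noise
variance and any field maps are treated as known, and the Gaussian
posterior shape is an approximation.

## Synthetic data

Two generators provide all test inputs, both pure functions of their
seed:

* `simulate_voxels()` draws independent single-voxel datasets — three
  contrasts (one MT) of five echoes; all four log-parameters and the
  log-TR and log-TE uniform on $[-5, 5]$; flip angles uniform on
  $[0, \pi/4]$; unit Gaussian noise. Echo times are sampled
  independently of TR (no $TE < TR$ constraint — the sampling scheme
  does not state one), so the benchmark covers physically implausible
  but numerically demanding corners.
* `make_phantom()` builds a 32³ piecewise-constant phantom of three
  nested ellipsoids with literature-style tissue values (inner,
  white-matter-like: $R_1 = 1.0$, $R_2^* = 20\,\mathrm{s}^{-1}$,
  $\delta = 0.02$, $A = 1000$; middle, grey-matter-like: 0.6, 15, 0.01,
  1100; outer, CSF-like: 0.25, 1, 0.001, 1500 — synthetic choices by
  this package, not measured values) and a 21/6/6-degree, 25 ms TR,
  2.3 ms echo-spacing protocol with 8/8/6 echoes. The default noise
  (Gaussian, $\sigma = 3$) puts the first-echo SNR near 25, similar to
  sub-millimetre in-vivo acquisitions. All four maps share one edge set
  by construction — exactly the structure the JTV prior rewards.

What the phantom does *not* emulate: anatomy-scale texture, partial
volume, field inhomogeneities, inter-scan motion, or Rician bias at low
SNR (Rician noise is available as an option). Passing phantom tests
therefore validates the estimator and solver machinery, not robustness
to those real-data effects.

## Problem sizes used by the test suite

The checked-in tests run the single-voxel benchmark at 200 voxels with
1000 iterations (10,000 for the basis comparison, where slow tails are
the phenomenon of interest), and phantom experiments at 32³ with 2/4/6
echoes; operator-level oracles (dense matrices, adjoints, PCG vs direct
solves) use 5³–6³ grids where dense linear algebra is exact and cheap.
These sizes reproduce every qualitative contrast of interest — the
choice of larger volumes changes runtimes, not conclusions.

## Known limitations

* Gaussian likelihood only; at low SNR the Rician mean shifts the fit
  (the phantom generator can produce Rician data to quantify this).
* No convergence proof for the residual-loaded Hessian in the
  multivariate case; the solver safeguard exists for exactly this
  reason.
* B1+/B1− fields are inputs, not estimands; imperfect spoiling is not
  modelled.
* The analytic intercept inversion requires a common TR across
  contrasts (the usual MPM situation); unequal-TR protocols would need
  rational approximations, which are out of scope.
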