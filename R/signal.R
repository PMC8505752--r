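#' Log-encoded SPGR parameters for one voxel
#'
#' The spoiled-gradient-echo (SPGR) forward model is parameterised by the
#' proton-density scaling `A`, the longitudinal relaxation rate `R1` (1/s),
#' the apparent transverse relaxation rate `R2*` (1/s) and the
#' magnetisation-transfer saturation `MTsat` (a fraction in (0,1)).
#' Internally each parameter is encoded on the whole real line:
#' `A = exp(a_tilde)`, `R1 = exp(r1_tilde)`, `R2* = exp(r2_tilde)` and
#' `MTsat = 1/(1 + exp(-delta_tilde))`. This makes the fit unconstrained and
#' unit-invariant (a change of unit is an additive shift of the log-map).
#'
#' @param a_tilde log proton-density scaling.
#' @param r1_tilde log longitudinal rate (log 1/s).
#' @param r2_tilde log apparent transverse rate (log 1/s).
#' @param delta_tilde logit of the MT saturation fraction.
#' @return an object of class `log_params` (named numeric vector).
#' @examples
#' p <- log_params(log(1000), log(1), log(20), logit(0.02))
#' exp(p[["r1_tilde"]])  # R1 in 1/s
#' @export
log_params <- function(a_tilde, r1_tilde, r2_tilde, delta_tilde = 0) {
  p <- c(a_tilde = as.numeric(a_tilde), r1_tilde = as.numeric(r1_tilde),
         r2_tilde = as.numeric(r2_tilde), delta_tilde = as.numeric(delta_tilde))
  if (!all(is.finite(p))) stop("log-parameters must be finite", call. = FALSE)
  class(p) <- "log_params"
  p
}

#' @rdname log_params
#' @export
logit <- function(p) log(p) - log1p(-p)

#' Acquisition parameters for one SPGR volume
#'
#' One volume is described by the quadruplet (flip angle, repetition time,
#' echo time, noise variance) plus a flag saying whether an off-resonance
#' magnetisation-transfer pulse was played. All values are in SI units
#' internally (radians, seconds); degree/millisecond conversion belongs to
#' the I/O layer ([read_series()]).
#'
#' @param flip excitation flip angle, radians, in `[0, pi/2]`.
#' @param tr repetition time, seconds, `> 0`.
#' @param te echo time, seconds, `>= 0`.
#' @param sigma2 noise variance in squared intensity units, `> 0`.
#' @param mt logical, `TRUE` if the volume is MT-weighted.
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(flip, tr, te, sigma2 = 1, mt = FALSE) {
  if (!is.finite(flip) || flip < 0 || flip > pi / 2 + 1e-12)
    stop("flip must be in [0, pi/2] radians", call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (!is.finite(te) || te < 0) stop("te must be >= 0", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  structure(list(flip = flip, tr = tr, te = te, sigma2 = sigma2,
                 mt = isTRUE(mt)),
            class = "acq_params")
}

# Vectorised SPGR kernel: signal, gradient and (full) Hessian of the signal
# with respect to the log/logit-encoded parameters. All arguments recycle.
# Where `mt` is FALSE the saturation is fixed to 0 exactly and the
# delta_tilde derivatives vanish identically.
#
# The closed forms were derived symbolically from
#   s = a sin(f) (1-d)(1-E) / (1 - (1-d) cos(f) E) * exp(-r2 te),
#   E = exp(-r1 tr),
# and are written in factored form so no 0/0 occurs at E -> 1 or d -> 0.
spgr_kernel <- function(a_t, r1_t, r2_t, d_t, flip, tr, te, mt,
                        hessian = FALSE, full = FALSE) {
  a  <- exp(pmin(a_t, 700))
  r1 <- exp(pmin(r1_t, 700))
  r2 <- exp(pmin(r2_t, 700))
  d  <- sigmoid(d_t) * as.numeric(mt)     # exact 0 for non-MT volumes
  m  <- 1 - d
  x1 <- pmin(r1 * tr, 700)                # r1*tr*E underflows cleanly
  E  <- exp(-x1)
  ca <- cos(flip); sa <- sin(flip)
  D  <- 1 - m * ca * E
  x2 <- pmin(r2 * te, 700)
  v  <- exp(-x2)
  s0 <- a * sa * m * (1 - E) / D          # signal at TE = 0
  s  <- s0 * v

  g_a  <- s
  g_r1 <- a * sa * m * v * x1 * E * (1 - m * ca) / D^2
  g_r2 <- -x2 * s
  g_dt <- -(d / D) * s
  out <- list(s = s, g_a = g_a, g_r1 = g_r1, g_r2 = g_r2, g_dt = g_dt)

  if (hessian) {
    out$h_aa   <- s
    out$h_r1r1 <- (1 - x1 * (1 + m * ca * E) / D) * g_r1
    out$h_r2r2 <- (1 - x2) * g_r2
    out$h_dtdt <- ((m - d - m * ca * E) / D) * g_dt
    if (full) {
      # mixed terms, needed by the |H|1 row-sum loading
      out$h_r1dt <- a * sa * v * x1 * E * (-d * m) *
        ((1 - 2 * m * ca) / D^2 + 2 * ca * E * m * (1 - m * ca) / D^3)
      out$h_ar1  <- g_r1
      out$h_ar2  <- g_r2
      out$h_adt  <- g_dt
      out$h_r1r2 <- -x2 * g_r1
      out$h_r2dt <- -x2 * g_dt
    }
  }
  out
}

.check_p_acq <- function(p, acq) {
  if (!inherits(p, "log_params")) stop("p must be a log_params object", call. = FALSE)
  if (!inherits(acq, "acq_params")) stop("acq must be an acq_params object", call. = FALSE)
  if (!all(is.finite(unclass(p)))) stop("non-finite log-parameters", call. = FALSE)
}

#' SPGR steady-state signal
#'
#' Evaluates the spoiled-gradient-echo steady-state magnitude signal
#' \deqn{s = A \sin\alpha \frac{(1-\delta)(1-e^{-R_1 TR})}
#'   {1-(1-\delta)\cos\alpha\, e^{-R_1 TR}} e^{-R_2^* TE}}
#' at the log-encoded parameters `p`. For volumes without an MT pulse
#' (`acq$mt == FALSE`) the saturation \eqn{\delta} is fixed to exactly 0.
#'
#' @param p [log_params()] for the voxel.
#' @param acq [acq_params()] for the volume.
#' @param flip_scale optional multiplicative B1+ efficiency applied to the
#'   nominal flip angle (default 1, ideal transmit field).
#' @return signal intensity, a nonnegative scalar.
#' @export
spgr_signal <- function(p, acq, flip_scale = 1) {
  .check_p_acq(p, acq)
  k <- spgr_kernel(p[["a_tilde"]], p[["r1_tilde"]], p[["r2_tilde"]],
                   p[["delta_tilde"]], acq$flip * flip_scale, acq$tr, acq$te,
                   acq$mt)
  k$s
}

#' Gradient of the SPGR signal in the log basis
#'
#' First derivatives of [spgr_signal()] with respect to
#' `(a_tilde, r1_tilde, r2_tilde, delta_tilde)`. The first component equals
#' the signal itself (`ds/da_tilde = s`) and the third equals
#' `-te * r2 * s`; for non-MT volumes the `delta_tilde` component is exactly
#' zero.
#'
#' @inheritParams spgr_signal
#' @return named numeric 4-vector.
#' @export
spgr_gradient <- function(p, acq, flip_scale = 1) {
  .check_p_acq(p, acq)
  k <- spgr_kernel(p[["a_tilde"]], p[["r1_tilde"]], p[["r2_tilde"]],
                   p[["delta_tilde"]], acq$flip * flip_scale, acq$tr, acq$te,
                   acq$mt)
  c(a_tilde = k$g_a, r1_tilde = k$g_r1, r2_tilde = k$g_r2,
    delta_tilde = k$g_dt)
}

#' Diagonal second derivatives of the SPGR signal
#'
#' `d2s/da_tilde2 = ds/da_tilde`, `d2s/dr2_tilde2 = (1 - te r2) ds/dr2_tilde`,
#' and analogous factored forms for the other two parameters.
#'
#' @inheritParams spgr_signal
#' @return named numeric 4-vector of second derivatives.
#' @export
spgr_hessian_diag <- function(p, acq, flip_scale = 1) {
  .check_p_acq(p, acq)
  k <- spgr_kernel(p[["a_tilde"]], p[["r1_tilde"]], p[["r2_tilde"]],
                   p[["delta_tilde"]], acq$flip * flip_scale, acq$tr, acq$te,
                   acq$mt, hessian = TRUE)
  c(a_tilde = k$h_aa, r1_tilde = k$h_r1r1, r2_tilde = k$h_r2r2,
    delta_tilde = k$h_dtdt)
}

#' Full 4x4 Hessian of the SPGR signal
#'
#' Symmetric matrix of all second derivatives of the signal with respect to
#' the log-encoded parameters, including mixed terms. Used by the row-sum
#' (`|H| 1`) diagonal loading.
#'
#' @inheritParams spgr_signal
#' @return 4x4 symmetric numeric matrix.
#' @export
spgr_hessian <- function(p, acq, flip_scale = 1) {
  .check_p_acq(p, acq)
  k <- spgr_kernel(p[["a_tilde"]], p[["r1_tilde"]], p[["r2_tilde"]],
                   p[["delta_tilde"]], acq$flip * flip_scale, acq$tr, acq$te,
                   acq$mt, hessian = TRUE, full = TRUE)
  H <- matrix(c(k$h_aa,  k$h_ar1,  k$h_ar2,  k$h_adt,
                k$h_ar1, k$h_r1r1, k$h_r1r2, k$h_r1dt,
                k$h_ar2, k$h_r1r2, k$h_r2r2, k$h_r2dt,
                k$h_adt, k$h_r1dt, k$h_r2dt, k$h_dtdt), 4, 4)
  dimnames(H) <- rep(list(c("a_tilde", "r1_tilde", "r2_tilde", "delta_tilde")), 2)
  H
}

#' Per-voxel negative log-likelihood, gradient and preconditioner
#'
#' For a set of observations \eqn{(x_i, \theta_i)} of one voxel, computes the
#' Gaussian negative log-likelihood
#' \eqn{\sum_i (x_i - s(\theta_i))^2 / (2\sigma_i^2)}, its gradient in the
#' log basis, and the positive semi-definite approximate Hessian
#' \deqn{\tilde P = \sum_i \frac{1}{\sigma_i^2}\left[ g_i g_i^T +
#'   |s_i - x_i| \, \mathrm{diag}|H_i| \right]}
#' which augments the Gauss-Newton (Fisher scoring) matrix with the absolute
#' residual times the absolute signal Hessian diagonal. With
#' `loading = "rowsum"` the diagonal `|H_i|` is replaced by the row sums of
#' the absolute full Hessian, `diag(|H_i| 1)`, the only variant guaranteed
#' to majorise the true Hessian.
#'
#' @param p [log_params()] for the voxel.
#' @param observations a data frame with columns `intensity`, `flip`, `tr`,
#'   `te`, `sigma2`, `mt` (one row per volume), or a list of
#'   `list(intensity =, acq = acq_params)` pairs.
#' @param loading `"diag"` (default) or `"rowsum"`.
#' @param flip_scale optional B1+ efficiency scaling of the flip angles.
#' @return list with elements `nll` (scalar), `gradient` (4-vector) and
#'   `preconditioner` (4x4 symmetric PSD matrix).
#' @export
voxel_objective_terms <- function(p, observations, loading = c("diag", "rowsum"),
                                  flip_scale = 1) {
  loading <- match.arg(loading)
  obs <- as_observation_frame(observations)
  if (nrow(obs) == 0L) stop("at least one observation is required", call. = FALSE)
  if (any(!is.finite(obs$sigma2) | obs$sigma2 <= 0))
    stop("all sigma2 must be finite and > 0", call. = FALSE)
  if (!all(is.finite(unclass(p)))) stop("non-finite log-parameters", call. = FALSE)
  k <- spgr_kernel(p[["a_tilde"]], p[["r1_tilde"]], p[["r2_tilde"]],
                   p[["delta_tilde"]], obs$flip * flip_scale, obs$tr, obs$te,
                   obs$mt, hessian = TRUE, full = TRUE)
  r <- k$s - obs$intensity
  iv <- 1 / obs$sigma2
  nll <- sum(r^2 * iv) / 2
  G <- cbind(k$g_a, k$g_r1, k$g_r2, k$g_dt)
  grad <- colSums(G * (r * iv))
  P <- crossprod(G * sqrt(iv))
  hd <- cbind(k$h_aa, k$h_r1r1, k$h_r2r2, k$h_dtdt)
  if (loading == "diag") {
    ld <- colSums(abs(hd) * (abs(r) * iv))
  } else {
    rowsums <- cbind(abs(k$h_aa)  + abs(k$h_ar1)  + abs(k$h_ar2)  + abs(k$h_adt),
                     abs(k$h_ar1) + abs(k$h_r1r1) + abs(k$h_r1r2) + abs(k$h_r1dt),
                     abs(k$h_ar2) + abs(k$h_r1r2) + abs(k$h_r2r2) + abs(k$h_r2dt),
                     abs(k$h_adt) + abs(k$h_r1dt) + abs(k$h_r2dt) + abs(k$h_dtdt))
    ld <- colSums(rowsums * (abs(r) * iv))
  }
  diag(P) <- diag(P) + ld
  nm <- c("a_tilde", "r1_tilde", "r2_tilde", "delta_tilde")
  names(grad) <- nm
  dimnames(P) <- list(nm, nm)
  list(nll = nll, gradient = grad, preconditioner = P)
}

# Normalise the two accepted observation representations to a data frame.
as_observation_frame <- function(observations) {
  if (is.data.frame(observations)) {
    need <- c("intensity", "flip", "tr", "te")
    if (!all(need %in% names(observations)))
      stop("observations need columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (is.null(observations$sigma2)) observations$sigma2 <- 1
    if (is.null(observations$mt)) observations$mt <- FALSE
    return(observations)
  }
  if (is.list(observations)) {
    rows <- lapply(observations, function(o) {
      acq <- o$acq
      data.frame(intensity = o$intensity, flip = acq$flip, tr = acq$tr,
                 te = acq$te, sigma2 = acq$sigma2, mt = acq$mt)
    })
    return(do.call(rbind, rows))
  }
  stop("unsupported observation container", call. = FALSE)
}
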