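# ESTATICS baselines: joint multi-contrast R2* estimation with one TE = 0
# intercept per contrast, followed by exact analytic recovery of A, R1 and
# MTsat from the intercepts when all TRs are equal.

#' Log-linear ESTATICS fit (LOGLIN)
#'
#' Solves `log x_{c,e} = b_c - r2 * te_{c,e}` jointly over all contrasts by
#' linear least squares in closed form: one log-intercept per contrast and
#' a single shared R2* decay. Intensities are clamped at a small positive
#' fraction of the maximum before the log (magnitude data can contain
#' zeros); the fitted decay is clamped positive before taking its log.
#'
#' @param observations data frame with columns `intensity`, `te`, `contrast`
#'   (integer contrast label).
#' @param clamp relative intensity clamp.
#' @return list with `intercepts` (log-intercepts, one per contrast),
#'   `r2_tilde` (log R2*) and `r2`.
#' @export
loglin_fit <- function(observations, clamp = 1e-6) {
  obs <- observations
  stopifnot(all(c("intensity", "te", "contrast") %in% names(obs)))
  if (length(unique(obs$te)) < 2L)
    stop("all echoes share a single TE: decay is unidentifiable",
         call. = FALSE)
  cid <- match(obs$contrast, sort(unique(obs$contrast)))
  C <- max(cid)
  y <- log(pmax(obs$intensity, clamp * max(obs$intensity)))
  X <- matrix(0, nrow(obs), C + 1L)
  X[cbind(seq_len(nrow(obs)), cid)] <- 1
  X[, C + 1L] <- -obs$te
  fit <- stats::lm.fit(X, y)
  if (fit$rank < C + 1L)
    stop("rank-deficient design: not enough distinct echo times",
         call. = FALSE)
  beta <- fit$coefficients
  r2 <- max(beta[C + 1L], 1e-12)
  list(intercepts = unname(beta[seq_len(C)]), r2_tilde = log(r2), r2 = r2)
}

#' Non-linear ESTATICS fit (NONLIN)
#'
#' Minimises the intensity-domain least squares
#' \eqn{\sum_{c,e} (x_{c,e} - e^{b_c - r_2 te_{c,e}})^2 / (2\sigma_c^2)}
#' by Newton iterations with the residual-loaded approximate Hessian
#' (Gauss-Newton plus `|residual| * |diag H|`), which keeps the
#' unregularised fit stable. Each step is safeguarded: accepted only if the
#' objective does not increase, halving up to `max_halving` times.
#'
#' @param observations data frame with columns `intensity`, `te`,
#'   `contrast` and optionally `sigma2` (per row; default 1).
#' @param init optional starting values, as returned by [loglin_fit()]
#'   (default: the log-linear solution).
#' @param max_iter,tol iteration cap and relative gain tolerance.
#' @param max_halving safeguard halvings per iteration.
#' @return list with `intercepts`, `r2_tilde`, `r2`, `objective`, `trace`
#'   (data frame of iteration, objective, gain).
#' @export
nonlin_fit <- function(observations, init = NULL, max_iter = 100,
                       tol = 1e-10, max_halving = 5) {
  obs <- observations
  if (is.null(obs$sigma2)) obs$sigma2 <- 1
  cid <- match(obs$contrast, sort(unique(obs$contrast)))
  C <- max(cid)
  if (is.null(init)) init <- loglin_fit(obs)
  theta <- c(init$intercepts, init$r2_tilde)
  iv <- 1 / obs$sigma2
  K <- C + 1L
  objective <- function(th) {
    s <- exp(th[cid] - exp(th[K]) * obs$te)
    sum((s - obs$intensity)^2 * iv) / 2
  }
  obj <- objective(theta)
  if (!is.finite(obj)) stop("non-finite objective at initialisation",
                            call. = FALSE)
  rows <- list(data.frame(iteration = 0L, objective = obj, gain = NA))
  for (it in seq_len(max_iter)) {
    r2 <- exp(theta[K])
    x2 <- r2 * obs$te
    s <- exp(theta[cid] - x2)
    r <- s - obs$intensity
    g_r2 <- -x2 * s
    grad <- numeric(K)
    P <- matrix(0, K, K)
    for (c in seq_len(C)) {
      in_c <- cid == c
      grad[c] <- sum(r[in_c] * iv[in_c] * s[in_c])
      P[c, c] <- sum(s[in_c]^2 * iv[in_c]) +
        sum(abs(r[in_c]) * iv[in_c] * abs(s[in_c]))
      P[c, K] <- P[K, c] <- sum(s[in_c] * g_r2[in_c] * iv[in_c])
    }
    grad[K] <- sum(r * iv * g_r2)
    P[K, K] <- sum(g_r2^2 * iv) +
      sum(abs(r) * iv * abs((1 - x2) * g_r2))
    step <- newton_step(grad, P)
    fac <- 1
    obj_new <- NA
    for (h in 0:max_halving) {
      cand <- theta - fac * step
      o <- objective(cand)
      if (is.finite(o) && o <= obj) { obj_new <- o; theta <- cand; break }
      fac <- fac / 2
    }
    if (is.na(obj_new)) break
    gain <- obj - obj_new
    obj <- obj_new
    rows[[length(rows) + 1L]] <-
      data.frame(iteration = it, objective = obj, gain = gain)
    if (gain < tol * (abs(rows[[1L]]$objective - obj) + 1e-300)) break
  }
  list(intercepts = unname(theta[seq_len(C)]), r2_tilde = theta[K],
       r2 = exp(theta[K]), objective = obj, trace = do.call(rbind, rows))
}

#' Exact analytic inversion of TE = 0 intercepts
#'
#' When all contrasts share one repetition time, the SPGR steady state at
#' TE = 0 is exactly linear in the helper variables `y = S / sin(flip)` and
#' `x = S / tan(flip)`: `y = A (1 - E) + E x` with `E = exp(-R1 TR)`. Two
#' non-MT intercepts at different flip angles therefore give
#' `E = (y1 - y2) / (x1 - x2)`, `A = (y1 - E x1) / (1 - E)` and
#' `R1 = -log(E) / TR` in closed form, without rational approximations.
#' Given `A` and `R1`, the MT-weighted intercept yields the saturation
#' in closed form from
#' `S = A sin(a) (1-d)(1-E) / (1 - (1-d) cos(a) E)`, i.e.
#' `1 - d = S / (A sin(a) (1-E) + S cos(a) E)`.
#'
#' Voxels with `E` outside (0, 1) (noise-dominated or degenerate) are
#' returned as `NaN` and counted in the `n_invalid` attribute.
#'
#' @param intercepts numeric matrix `N x C` (or vector, one voxel) of
#'   *linear-scale* TE = 0 intercepts `S_c = exp(b_c)`.
#' @param flips flip angles, radians, one per contrast.
#' @param tr common repetition time, seconds.
#' @param mt logical per contrast; exactly two non-MT contrasts are
#'   required, at most one MT contrast.
#' @return list with vectors `A`, `R1`, `MTsat` (`MTsat` is `NA` without an
#'   MT contrast) and attribute-like field `n_invalid`.
#' @export
intercepts_to_parameters <- function(intercepts, flips, tr,
                                     mt = c(FALSE, FALSE, TRUE)[seq_along(flips)]) {
  if (is.null(dim(intercepts)))
    intercepts <- matrix(intercepts, nrow = 1L)
  C <- ncol(intercepts)
  stopifnot(length(flips) == C, length(mt) == C)
  non_mt <- which(!mt)
  if (length(non_mt) != 2L)
    stop("exactly two non-MT contrasts (PD- and T1-weighted) are required",
         call. = FALSE)
  if (abs(flips[non_mt[1]] - flips[non_mt[2]]) < 1e-12)
    stop("the two non-MT contrasts must have different flip angles",
         call. = FALSE)
  i1 <- non_mt[1]; i2 <- non_mt[2]
  S1 <- intercepts[, i1]; S2 <- intercepts[, i2]
  y1 <- S1 / sin(flips[i1]); y2 <- S2 / sin(flips[i2])
  x1 <- S1 / tan(flips[i1]); x2 <- S2 / tan(flips[i2])
  dx <- x1 - x2
  bad_dx <- abs(dx) < 1e-300
  dx[bad_dx] <- NA
  E <- (y1 - y2) / dx
  invalid <- bad_dx | !is.finite(E) | E <= 0 | E >= 1
  E[invalid] <- NA
  A <- (y1 - E * x1) / (1 - E)
  R1 <- -log(E) / tr
  MTsat <- rep(NA_real_, length(A))
  if (any(mt)) {
    imt <- which(mt)[1L]
    Smt <- intercepts[, imt]
    am <- flips[imt]
    one_minus_d <- Smt / (A * sin(am) * (1 - E) + Smt * cos(am) * E)
    MTsat <- 1 - one_minus_d
  }
  A[invalid] <- NaN; R1[invalid] <- NaN; MTsat[invalid] <- NaN
  list(A = A, R1 = R1, MTsat = MTsat, n_invalid = sum(invalid))
}

#' Synthesise TE = 0 intercepts from quantitative parameters
#'
#' Forward counterpart of [intercepts_to_parameters()]: evaluates the
#' TE = 0 SPGR steady state for each contrast.
#'
#' @param A,R1,MTsat parameter vectors (recycled).
#' @param flips,tr,mt protocol, as in [intercepts_to_parameters()].
#' @return matrix `N x C` of intercepts.
#' @export
parameters_to_intercepts <- function(A, R1, MTsat, flips, tr,
                                     mt = c(FALSE, FALSE, TRUE)[seq_along(flips)]) {
  n <- max(length(A), length(R1), length(MTsat))
  A <- rep_len(A, n); R1 <- rep_len(R1, n); MTsat <- rep_len(MTsat, n)
  E <- exp(-R1 * tr)
  out <- matrix(0, n, length(flips))
  for (c in seq_along(flips)) {
    d <- if (mt[c]) MTsat else 0
    out[, c] <- A * sin(flips[c]) * (1 - d) * (1 - E) /
      (1 - (1 - d) * cos(flips[c]) * E)
  }
  out
}
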