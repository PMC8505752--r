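#' Simulate randomised single-voxel SPGR datasets
#'
#' Draws independent virtual voxels, each with its own parameters and
#' acquisition settings: the four log/logit-encoded tissue parameters and
#' the log repetition and echo times are uniform on `log_range`
#' (default \[-5, 5\]), flip angles are uniform on `flip_range` (default
#' \[0, pi/4\]), and Gaussian noise of variance `sigma2` (default 1) is
#' added to the noiseless signals. Each voxel has `n_contrasts` contrasts
#' (one TR and flip angle per contrast, the last one MT-weighted) with
#' `n_echoes` echo times each, sampled independently of TR.
#'
#' @param n_voxels number of voxels.
#' @param n_contrasts contrasts per voxel (default 3, one with an MT pulse).
#' @param n_echoes echoes per contrast (default 5).
#' @param log_range range of the uniform log-parameter sampling.
#' @param flip_range range of the uniform flip-angle sampling (radians).
#' @param sigma2 Gaussian noise variance (0 gives noiseless signals).
#' @param seed RNG seed; the seed fully determines the output.
#' @return list with `truth` (`n_voxels x 4` matrix of log-parameters) and
#'   `observations` (data frame with columns `voxel`, `contrast`, `echo`,
#'   `flip`, `tr`, `te`, `mt`, `sigma2`, `signal`, `intensity`).
#' @export
simulate_voxels <- function(n_voxels = 1000, n_contrasts = 3, n_echoes = 5,
                            log_range = c(-5, 5), flip_range = c(0, pi / 4),
                            sigma2 = 1, seed = 0) {
  stopifnot(n_voxels >= 1, n_contrasts >= 1, n_echoes >= 1,
            all(is.finite(log_range)), all(is.finite(flip_range)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  V <- n_voxels; C <- n_contrasts; E <- n_echoes
  runifr <- function(n, r) stats::runif(n, r[1], r[2])
  truth <- cbind(a_tilde = runifr(V, log_range),
                 r1_tilde = runifr(V, log_range),
                 r2_tilde = runifr(V, log_range),
                 delta_tilde = runifr(V, log_range))
  flip_c <- matrix(runifr(V * C, flip_range), V, C)
  tr_c <- matrix(exp(runifr(V * C, log_range)), V, C)
  te <- array(exp(runifr(V * C * E, log_range)), c(V, C, E))
  mt_c <- c(rep(FALSE, C - 1L), TRUE)

  idx <- expand.grid(voxel = seq_len(V), echo = seq_len(E),
                     contrast = seq_len(C))
  obs <- data.frame(voxel = idx$voxel, contrast = idx$contrast,
                    echo = idx$echo)
  obs$flip <- flip_c[cbind(obs$voxel, obs$contrast)]
  obs$tr <- tr_c[cbind(obs$voxel, obs$contrast)]
  obs$te <- te[cbind(obs$voxel, obs$contrast, obs$echo)]
  obs$mt <- mt_c[obs$contrast]
  obs$sigma2 <- if (sigma2 > 0) sigma2 else 1
  k <- spgr_kernel(truth[obs$voxel, 1], truth[obs$voxel, 2],
                   truth[obs$voxel, 3], truth[obs$voxel, 4],
                   obs$flip, obs$tr, obs$te, obs$mt)
  obs$signal <- k$s
  obs$intensity <- obs$signal +
    if (sigma2 > 0) stats::rnorm(nrow(obs), sd = sqrt(sigma2)) else 0
  obs <- obs[order(obs$voxel, obs$contrast, obs$echo), ]
  rownames(obs) <- NULL
  list(truth = truth, observations = obs)
}

#' Reshape a tidy observation table to per-voxel matrices
#'
#' Converts the long-format observation table of [simulate_voxels()] into
#' the `V x O` matrices consumed by the batched fitting engine.
#'
#' @param observations data frame as produced by [simulate_voxels()].
#' @return list of matrices `intensity`, `flip`, `tr`, `te`, `sigma2`, `mt`.
#' @export
observation_matrices <- function(observations) {
  obs <- observations[order(observations$voxel, observations$contrast,
                            observations$echo), ]
  vox <- unique(obs$voxel)
  V <- length(vox)
  O <- nrow(obs) / V
  if (O != round(O))
    stop("all voxels must have the same number of observations", call. = FALSE)
  shape <- function(col) matrix(col, nrow = V, ncol = O, byrow = TRUE)
  list(intensity = shape(obs$intensity), flip = shape(obs$flip),
       tr = shape(obs$tr), te = shape(obs$te), sigma2 = shape(obs$sigma2),
       mt = shape(obs$mt))
}

#' Default multi-echo VFA protocol for the synthetic phantom
#'
#' Three multi-echo gradient-echo contrasts: a T1-weighted series (21
#' degrees), a PD-weighted series (6 degrees) and an MT-weighted series
#' (6 degrees, off-resonance pulse on), all with a 25 ms TR and a 2.3 ms
#' echo spacing; 8/8/6 echoes respectively.
#'
#' @return list with elements `flip_deg`, `tr`, `n_echoes`, `echo_spacing`,
#'   `mt`.
#' @export
default_protocol <- function() {
  list(flip_deg = c(21, 6, 6), tr = 0.025, n_echoes = c(8L, 8L, 6L),
       echo_spacing = 0.0023, mt = c(FALSE, FALSE, TRUE))
}

#' Piecewise-constant 3-D phantom with shared edges
#'
#' Builds a synthetic multi-parameter phantom of three nested ellipsoidal
#' regions with tissue-like values (inner, white-matter-like: R1 = 1.0/s,
#' R2* = 20/s, MTsat = 0.02, A = 1000; middle, grey-matter-like: 0.6/s,
#' 15/s, 0.01, 1100; outer, CSF-like: 0.25/s, 1/s, 0.001, 1500). All four
#' parameter maps are piecewise constant with the *same* edge set, the
#' spatial structure the joint total variation prior assumes. Echo volumes
#' are generated through the SPGR forward model; Gaussian (default) or
#' Rician noise of standard deviation `sigma` can be added. This phantom is
#' synthetic plumbing for testing; it emulates the geometry of a
#' multi-parameter mapping session, not real anatomy.
#'
#' @param dim grid size, length 3 (default `c(32, 32, 32)`).
#' @param voxel_size physical voxel spacing in mm (default 1 mm isotropic).
#' @param protocol acquisition protocol, see [default_protocol()].
#' @param sigma noise standard deviation per contrast (scalar recycled;
#'   default 3, giving first-echo SNR around 25 with the default values).
#' @param noise `"gaussian"`, `"rician"` or `"none"`.
#' @param seed RNG seed.
#' @param affine optional 4x4 voxel-to-world matrix (default: scaled
#'   identity from `voxel_size`).
#' @return list with `truth` (a [map_stack()] of the four log-parameter
#'   maps), `series` (list of [contrast_series()]), `regions` (integer
#'   array of region labels), and `values` (the per-region parameter table).
#' @export
make_phantom <- function(dim = c(32, 32, 32), voxel_size = c(1, 1, 1),
                         protocol = default_protocol(), sigma = 3,
                         noise = c("gaussian", "rician", "none"), seed = 0,
                         affine = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(dim) == 3, all(dim >= 4))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  C <- length(protocol$flip_deg)
  sigma <- rep_len(sigma, C)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dim - 1) / 2
  }

  # nested ellipsoids; region 3 = outer (fills the rest of the grid)
  ctr <- (dim + 1) / 2
  g <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                   k = seq_len(dim[3]))
  rho2 <- ((g$i - ctr[1]) / (0.45 * dim[1]))^2 +
          ((g$j - ctr[2]) / (0.45 * dim[2]))^2 +
          ((g$k - ctr[3]) / (0.45 * dim[3]))^2
  regions <- array(3L, dim)
  regions[rho2 <= 1] <- 2L
  regions[rho2 <= (0.55)^2] <- 1L

  values <- data.frame(region = 1:3,
                       tissue = c("wm-like", "gm-like", "csf-like"),
                       A = c(1000, 1100, 1500),
                       R1 = c(1.0, 0.6, 0.25),
                       R2s = c(20, 15, 1),
                       MTsat = c(0.02, 0.01, 0.001))
  maps <- array(0, c(dim, 4))
  maps[, , , 1] <- array(log(values$A[regions]), dim)
  maps[, , , 2] <- array(log(values$R1[regions]), dim)
  maps[, , , 3] <- array(log(values$R2s[regions]), dim)
  maps[, , , 4] <- array(logit(values$MTsat[regions]), dim)
  truth <- map_stack(maps, affine = affine, voxel_size = voxel_size)

  series <- vector("list", C)
  for (ci in seq_len(C)) {
    ne <- protocol$n_echoes[ci]
    tes <- protocol$echo_spacing * seq_len(ne)
    flip <- protocol$flip_deg[ci] * pi / 180
    echoes <- vector("list", ne)
    for (e in seq_len(ne)) {
      k <- spgr_kernel(maps[, , , 1], maps[, , , 2], maps[, , , 3],
                       maps[, , , 4], flip, protocol$tr, tes[e],
                       protocol$mt[ci])
      s <- array(k$s, dim)
      vol <- switch(noise,
        none = s,
        gaussian = s + array(stats::rnorm(prod(dim), sd = sigma[ci]), dim),
        rician = {
          re <- s + stats::rnorm(prod(dim), sd = sigma[ci])
          im <- stats::rnorm(prod(dim), sd = sigma[ci])
          array(sqrt(re^2 + im^2), dim)
        })
      echoes[[e]] <- vol
    }
    series[[ci]] <- contrast_series(echoes, flip = flip, tr = protocol$tr,
                                    te = tes, mt = protocol$mt[ci],
                                    sigma2 = if (noise == "none") NULL
                                             else sigma[ci]^2,
                                    affine = affine,
                                    voxel_size = voxel_size)
  }
  list(truth = truth, series = series, regions = regions, values = values)
}

# Save/restore the global RNG state so generators are pure in their seed.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
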