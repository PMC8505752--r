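# Joint total variation: energy, IRLS bound, weights, and the discrete
# gradient operators the solver needs. Differences use replicate-edge
# (Neumann) boundaries, so constant maps are in the null space.

# Shift helpers along one axis of a 3-D array (replicate / zero padding).
ax_index <- function(n, by, edge = c("replicate", "zero")) {
  edge <- match.arg(edge)
  idx <- seq_len(n) + by
  if (edge == "replicate") pmin(pmax(idx, 1L), n) else idx
}

ax_take <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

ax_zero_slice <- function(a, axis, which = c("first", "last")) {
  which <- match.arg(which)
  n <- dim(a)[axis]
  i <- if (which == "first") 1L else n
  switch(axis, a[i, , ] <- 0, a[, i, ] <- 0, a[, , i] <- 0)
  a
}

#' Forward and backward finite differences of a 3-D field
#'
#' Returns the six first differences (forward and backward along each axis)
#' about every voxel, divided by the physical voxel size. Differences across
#' the boundary are zero (replicate-edge rule), so a constant field has all
#' differences zero.
#'
#' @param vol 3-D numeric array.
#' @param voxel_size length-3 spacing (mm).
#' @return 4-D array `dim(vol) x 6`, ordered forward x/y/z then backward
#'   x/y/z.
#' @export
finite_differences <- function(vol, voxel_size = c(1, 1, 1)) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  out <- array(0, c(d, 6L))
  for (ax in 1:3) {
    h <- voxel_size[ax]
    fwd <- (ax_take(vol, ax, ax_index(d[ax], 1L)) - vol) / h
    bwd <- (vol - ax_take(vol, ax, ax_index(d[ax], -1L))) / h
    out[, , , ax] <- fwd       # replicate edge makes the last slice 0
    out[, , , ax + 3L] <- bwd  # and the first slice 0
  }
  out
}

#' Adjoint of [finite_differences()]
#'
#' Maps a 6-channel difference field back to a scalar field such that
#' `sum(finite_differences(u) * v) == sum(u * finite_differences_adjoint(v))`
#' exactly (up to rounding).
#'
#' @param d 4-D array `nx x ny x nz x 6`.
#' @param voxel_size length-3 spacing (mm).
#' @return 3-D numeric array.
#' @export
finite_differences_adjoint <- function(d, voxel_size = c(1, 1, 1)) {
  dd <- dim(d)
  stopifnot(length(dd) == 4L, dd[4L] == 6L)
  dims <- dd[1:3]
  out <- array(0, dims)
  for (ax in 1:3) {
    h <- voxel_size[ax]
    n <- dims[ax]
    # forward rows: row i = (-1 at i, +1 at i+1)/h, zero row at i = n
    z <- array(d[, , , ax], dims)
    zm <- ax_zero_slice(z, ax, "last")
    zpad <- ax_zero_slice(ax_take(z, ax, ax_index(n, -1L)), ax, "first")
    # note: the shifted-down copy must not reuse the replicated edge value
    out <- out + (zpad - zm) / h
    # backward rows: row i = (+1 at i, -1 at i-1)/h, zero row at i = 1
    z <- array(d[, , , ax + 3L], dims)
    zm <- ax_zero_slice(z, ax, "first")
    zup <- ax_zero_slice(ax_take(z, ax, ax_index(n, 1L)), ax, "last")
    out <- out + (zm - zup) / h
  }
  out
}

# Per-voxel squared gradient magnitude pooled across channels:
# t_n = sum_k lambda_k ||G_n y_k||^2.
jtv_pooled_sq <- function(maps, cfg) {
  d <- dim(maps)
  K <- d[4L]
  lambda <- rep_len(cfg$lambda, K)
  t <- array(0, d[1:3])
  for (k in seq_len(K)) {
    if (lambda[k] == 0) next
    g <- finite_differences(array(maps[, , , k], d[1:3]), cfg$voxel_size)
    for (j in 1:6) t <- t + lambda[k] * g[, , , j]^2
  }
  t
}

#' Joint total variation energy
#'
#' \deqn{\mathrm{JTV}(Y) = \sum_n \sqrt{\sum_k \lambda_k \|G_n y_k\|^2}}
#' where \eqn{G_n} extracts the six forward/backward finite differences
#' about voxel `n`. Pooling the channels inside the square root shares the
#' sparsity pattern (the edges) across parameter maps; with a single
#' channel it reduces to classical total variation.
#'
#' @param maps 4-D array or [map_stack()] (`K` channels).
#' @param cfg a [jtv_config()].
#' @return nonnegative scalar; 0 iff all maps are constant.
#' @export
jtv_energy <- function(maps, cfg) {
  sum(sqrt(jtv_pooled_sq(maps, cfg)))
}

#' Closed-form IRLS weight update
#'
#' The IRLS bound
#' \deqn{\sqrt{t_n} = \min_{w_n>0} \frac{1}{2 w_n} + \frac{w_n}{2} t_n}
#' is tight at \eqn{w_n = t_n^{-1/2}}. Exactly flat voxels are guarded by
#' clamping \eqn{t_n} below at `eps_rel` times the median nonzero value
#' (or an absolute floor when the whole field is flat), keeping the weights
#' finite.
#'
#' @param maps 4-D array or [map_stack()].
#' @param cfg a [jtv_config()].
#' @param eps_rel relative clamp for flat voxels.
#' @return 3-D array of strictly positive weights.
#' @export
irls_weight_update <- function(maps, cfg, eps_rel = 1e-10) {
  t <- jtv_pooled_sq(maps, cfg)
  nz <- t[t > 0]
  floor_t <- if (length(nz)) eps_rel * stats::median(nz) else 1e-10
  1 / sqrt(pmax(t, floor_t))
}

#' Evaluate the IRLS quadratic bound at given weights
#'
#' `sum_n [ 1/(2 w_n) + (w_n/2) t_n ]`; majorises [jtv_energy()] for any
#' positive weights, with equality at the weights from
#' [irls_weight_update()].
#'
#' @param maps 4-D array or [map_stack()].
#' @param w 3-D positive weight field.
#' @param cfg a [jtv_config()].
#' @return scalar bound value.
#' @export
jtv_bound <- function(maps, w, cfg) {
  t <- jtv_pooled_sq(maps, cfg)
  sum(1 / (2 * w) + w * t / 2)
}

#' Apply the weighted regularisation operator
#'
#' Computes `L y` channel-wise, with
#' `L = lambda_k * G' W G` and `W = diag(w)` replicated over the six
#' difference directions. This is the gradient of the quadratic IRLS bound
#' `(1/2) y' L y`.
#'
#' @param maps 4-D array or [map_stack()] (`K` channels).
#' @param w 3-D positive weight field.
#' @param cfg a [jtv_config()].
#' @return 4-D array of the same shape as `maps`.
#' @export
apply_regulariser <- function(maps, w, cfg) {
  d <- dim(maps)
  K <- d[4L]
  lambda <- rep_len(cfg$lambda, K)
  out <- array(0, d)
  for (k in seq_len(K)) {
    if (lambda[k] == 0) next
    g <- finite_differences(array(maps[, , , k], d[1:3]), cfg$voxel_size)
    for (j in 1:6) g[, , , j] <- g[, , , j] * w
    out[, , , k] <- lambda[k] *
      finite_differences_adjoint(g, cfg$voxel_size)
  }
  out
}

#' Exact diagonal of the regularisation operator
#'
#' The diagonal of `lambda_k * G' W G`, obtained by convolving the weight
#' field with a small cross-shaped kernel (per axis: own weight where a
#' difference row exists, plus the neighbours' weights), divided by the
#' squared voxel size. Used to complete the preconditioner of the conjugate
#' gradient solver and the Laplace variance maps.
#'
#' @param w 3-D positive weight field.
#' @param cfg a [jtv_config()].
#' @param K number of channels.
#' @return 4-D array `dim(w) x K`.
#' @export
regulariser_diagonal <- function(w, cfg, K = 4L) {
  d <- dim(w)
  lambda <- rep_len(cfg$lambda, K)
  base <- array(0, d)
  for (ax in 1:3) {
    h2 <- cfg$voxel_size[ax]^2
    n <- d[ax]
    own_fwd <- ax_zero_slice(w, ax, "last")    # forward row exists if i < n
    own_bwd <- ax_zero_slice(w, ax, "first")   # backward row exists if i > 1
    w_prev <- ax_zero_slice(ax_take(w, ax, ax_index(n, -1L)), ax, "first")
    w_next <- ax_zero_slice(ax_take(w, ax, ax_index(n, 1L)), ax, "last")
    base <- base + (own_fwd + own_bwd + w_prev + w_next) / h2
  }
  out <- array(0, c(d, K))
  for (k in seq_len(K)) out[, , , k] <- lambda[k] * base
  out
}
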