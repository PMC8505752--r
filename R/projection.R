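# Spatial projection between the reconstruction grid and an acquisition
# grid. Reslicing is trilinear interpolation, encoded once as a sparse
# matrix so that the push operation is its exact adjoint (transpose).

#' Build a reslicing operator between two oriented grids
#'
#' Maps a field defined on the source (reconstruction) grid to the target
#' (acquisition) grid by trilinear interpolation through the two
#' voxel-to-world affines. Samples falling outside the source field of view
#' receive (and, through the adjoint, contribute) zero. When the two grids
#' are identical the operator short-circuits to the identity.
#'
#' @param src_dim,src_affine source grid size and 4x4 voxel-to-world matrix
#'   (0-based voxel indices).
#' @param dst_dim,dst_affine target grid size and affine.
#' @return object of class `projection_operator`.
#' @export
projection_operator <- function(src_dim, src_affine, dst_dim, dst_affine) {
  if (identical(as.integer(src_dim), as.integer(dst_dim)) &&
      isTRUE(all.equal(src_affine, dst_affine, tolerance = 1e-10))) {
    return(structure(list(identity = TRUE, src_dim = src_dim,
                          dst_dim = dst_dim), class = "projection_operator"))
  }
  if (abs(det(src_affine)) < 1e-12)
    stop("source affine is not invertible", call. = FALSE)
  M <- prod(dst_dim); N <- prod(src_dim)
  # 0-based voxel coordinates of every target voxel, mapped into source space
  g <- as.matrix(expand.grid(i = seq_len(dst_dim[1]) - 1,
                             j = seq_len(dst_dim[2]) - 1,
                             k = seq_len(dst_dim[3]) - 1))
  A <- solve(src_affine) %*% dst_affine
  src <- cbind(g, 1) %*% t(A)   # M x 4, continuous source voxel coords
  f <- floor(src[, 1:3])
  w <- src[, 1:3] - f           # fractional part in [0,1)
  ii <- numeric(0); jj <- numeric(0); xx <- numeric(0)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    vi <- f[, 1] + cx; vj <- f[, 2] + cy; vk <- f[, 3] + cz
    wt <- (if (cx) w[, 1] else 1 - w[, 1]) *
          (if (cy) w[, 2] else 1 - w[, 2]) *
          (if (cz) w[, 3] else 1 - w[, 3])
    inside <- vi >= 0 & vi <= src_dim[1] - 1 &
              vj >= 0 & vj <= src_dim[2] - 1 &
              vk >= 0 & vk <= src_dim[3] - 1 & wt > 0
    if (!any(inside)) next
    col <- vi[inside] + src_dim[1] * (vj[inside] + src_dim[2] * vk[inside]) + 1
    ii <- c(ii, which(inside)); jj <- c(jj, col); xx <- c(xx, wt[inside])
  }
  Psi <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M, N))
  structure(list(identity = FALSE, Psi = Psi, src_dim = src_dim,
                 dst_dim = dst_dim), class = "projection_operator")
}

#' Reslice a field to the acquisition grid (pull)
#'
#' @param field 3-D array on the source grid (or 4-D stack; channels are
#'   resliced independently).
#' @param op a [projection_operator()].
#' @return array on the target grid.
#' @export
pull <- function(field, op) {
  if (op$identity) return(field)
  one <- function(v) array(as.numeric(op$Psi %*% as.vector(v)), op$dst_dim)
  if (length(dim(field)) == 4L) {
    K <- dim(field)[4L]
    out <- array(0, c(op$dst_dim, K))
    for (k in seq_len(K)) out[, , , k] <- one(field[, , , k])
    out
  } else one(field)
}

#' Adjoint reslicing to the reconstruction grid (push)
#'
#' Exact adjoint (transpose) of [pull()]: interpolation weights are
#' splatted back onto the source grid, so
#' `sum(pull(u) * v) == sum(u * push(v))` identically.
#'
#' @param field 3-D array (or 4-D stack) on the target grid.
#' @param op a [projection_operator()].
#' @return array on the source grid.
#' @export
push <- function(field, op) {
  if (op$identity) return(field)
  one <- function(v)
    array(as.numeric(Matrix::crossprod(op$Psi, as.vector(v))), op$src_dim)
  if (length(dim(field)) == 4L) {
    K <- dim(field)[4L]
    out <- array(0, c(op$src_dim, K))
    for (k in seq_len(K)) out[, , , k] <- one(field[, , , k])
    out
  } else one(field)
}
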