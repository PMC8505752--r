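# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Solve many small symmetric positive-definite linear systems
#'
#' Factorises `N` small `K x K` symmetric positive (semi-)definite blocks by
#' Cholesky decomposition, vectorised across blocks, and solves one
#' right-hand side per block. This is the work-horse behind per-voxel Newton
#' steps, the conjugate-gradient preconditioner and Laplace variance maps.
#'
#' A relative ridge `eps * mean(diag)` (plus a tiny absolute floor) is added
#' to each diagonal before factorisation so that blocks with inert rows
#' (for example the MT-saturation row when no MT contrast is present)
#' remain solvable.
#'
#' @param H numeric array `N x K x K` of symmetric blocks.
#' @param B numeric matrix `N x K` of right-hand sides.
#' @param eps relative diagonal loading.
#' @return numeric matrix `N x K`, the per-block solutions.
#' @keywords internal
block_solve <- function(H, B, eps = 1e-8) {
  dn <- dim(H)
  N <- dn[1L]; K <- dn[2L]
  L <- block_chol(H, eps = eps)
  block_chol_solve(L, B)
}

# Cholesky factors of N small SPD blocks (lower triangular), vectorised.
block_chol <- function(H, eps = 1e-8) {
  dn <- dim(H)
  N <- dn[1L]; K <- dn[2L]
  dmean <- 0
  for (k in seq_len(K)) dmean <- dmean + H[, k, k]
  load <- (eps / K) * dmean + 1e-300
  L <- array(0, dim = c(N, K, K))
  for (j in seq_len(K)) {
    v <- H[, j, j] + load
    if (j > 1L) for (k in seq_len(j - 1L)) v <- v - L[, j, k]^2
    # PSD blocks can dip below zero by rounding; clamp to a tiny positive
    v <- pmax(v, 1e-12 * (abs(H[, j, j]) + load) + 1e-300)
    L[, j, j] <- sqrt(v)
    if (j < K) {
      for (i in (j + 1L):K) {
        u <- H[, i, j]
        if (j > 1L) for (k in seq_len(j - 1L)) u <- u - L[, i, k] * L[, j, k]
        L[, i, j] <- u / L[, j, j]
      }
    }
  }
  L
}

# Solve L L' x = b given batched Cholesky factors.
block_chol_solve <- function(L, B) {
  K <- dim(L)[2L]
  Y <- matrix(0, nrow = dim(L)[1L], ncol = K)
  for (j in seq_len(K)) {
    u <- B[, j]
    if (j > 1L) for (k in seq_len(j - 1L)) u <- u - L[, j, k] * Y[, k]
    Y[, j] <- u / L[, j, j]
  }
  X <- matrix(0, nrow = dim(L)[1L], ncol = K)
  for (j in rev(seq_len(K))) {
    u <- Y[, j]
    if (j < K) for (k in (j + 1L):K) u <- u - L[, k, j] * X[, k]
    X[, j] <- u / L[, j, j]
  }
  X
}

# Diagonal of the inverse of each block: K solves with unit right-hand sides.
block_inverse_diag <- function(H, eps = 1e-8) {
  dn <- dim(H)
  N <- dn[1L]; K <- dn[2L]
  L <- block_chol(H, eps = eps)
  out <- matrix(0, N, K)
  for (k in seq_len(K)) {
    e <- matrix(0, N, K)
    e[, k] <- 1
    out[, k] <- block_chol_solve(L, e)[, k]
  }
  out
}

# Multiply batched symmetric blocks by batched vectors: (H x)[, i].
block_mult <- function(H, X) {
  K <- dim(H)[2L]
  out <- matrix(0, dim(H)[1L], K)
  for (i in seq_len(K)) {
    v <- 0
    for (j in seq_len(K)) v <- v + H[, i, j] * X[, j]
    out[, i] <- v
  }
  out
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
  invisible(x)
}
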