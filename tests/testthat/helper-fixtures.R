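# Shared fixtures: moderate-range random draws keep finite-difference
# oracles numerically meaningful (signals neither underflow nor saturate).

rand_log_params <- function(rng_fun = stats::runif) {
  log_params(rng_fun(1, -2, 2), rng_fun(1, -2, 2), rng_fun(1, -2, 2),
             rng_fun(1, -2, 2))
}

rand_acq <- function(mt = TRUE) {
  acq_params(flip = stats::runif(1, 0.05, pi / 2 - 0.05),
             tr = stats::runif(1, 0.005, 1),
             te = stats::runif(1, 0, 1),
             sigma2 = stats::runif(1, 0.5, 2),
             mt = mt)
}

# Central finite differences of f at x (vector input, scalar output).
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

as_lp <- function(x) log_params(x[1], x[2], x[3], x[4])

# Dense matrix of a linear operator (for small-grid oracles).
dense_operator <- function(op_fun, n_in, n_out = n_in) {
  M <- matrix(0, n_out, n_in)
  for (j in seq_len(n_in)) {
    e <- numeric(n_in); e[j] <- 1
    M[, j] <- op_fun(e)
  }
  M
}

# A small noiseless multi-contrast observation set from known parameters.
make_voxel_obs <- function(p, sigma2 = 1, seed = NULL, noise_sd = 0) {
  if (!is.null(seed)) set.seed(seed)
  flips <- c(21, 6, 6) * pi / 180
  mts <- c(FALSE, FALSE, TRUE)
  te <- 0.0023 * (1:5)
  rows <- list()
  for (c in 1:3) for (e in 1:5) {
    acq <- acq_params(flips[c], 0.025, te[e], sigma2, mts[c])
    s <- spgr_signal(p, acq)
    rows[[length(rows) + 1L]] <-
      data.frame(intensity = s + stats::rnorm(1, 0, noise_sd),
                 flip = acq$flip, tr = acq$tr, te = acq$te,
                 sigma2 = sigma2, mt = acq$mt)
  }
  do.call(rbind, rows)
}
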