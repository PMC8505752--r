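# Full-volume machinery: noise estimation, initialisation, assembly,
# PCG solves and the ML/MAP fits on small phantoms.

test_that("Rician mixture recovers a known noise level", {
  set.seed(601)
  n <- 4e4
  bg <- sqrt(rnorm(n, 0, 5)^2 + rnorm(n, 0, 5)^2)        # nu = 0, sigma = 5
  fg <- sqrt((100 + rnorm(n, 0, 5))^2 + rnorm(n, 0, 5)^2) # nu = 100
  fit <- rician_mixture(c(bg, fg))
  expect_lt(abs(sqrt(fit$sigma2) - 5) / 5, 0.1)
  expect_lt(abs(fit$fg_mean - 100) / 100, 0.02)
  # high-SNR foreground is approximately Gaussian: location within 1%
  expect_lt(abs(max(fit$nu) - 100) / 100, 0.01)
  expect_error(rician_mixture(rep(3, 100)), "degenerate")
})

test_that("series noise combines echoes by geometric mean", {
  set.seed(602)
  mk_vol <- function(sig) {
    s <- array(0, c(12, 12, 12))
    s[4:9, 4:9, 4:9] <- 100
    array(sqrt((s + rnorm(length(s), 0, sig))^2 +
                 rnorm(length(s), 0, sig)^2), dim(s))
  }
  sr <- contrast_series(list(mk_vol(2), mk_vol(3)), flip = 0.3, tr = 0.025,
                        te = c(0.002, 0.004))
  est <- estimate_noise(sr)
  expect_equal(est$sigma2, exp(mean(log(est$per_echo$sigma2))),
               tolerance = 1e-12)
  expect_lt(abs(sqrt(est$sigma2) - sqrt(6)) / sqrt(6), 0.25)
})

test_that("initial maps are constant and scale-equivariant", {
  ph <- make_phantom(dim = c(8, 8, 8), noise = "none")
  init <- initialize_maps(ph$series)
  for (k in 1:4) expect_equal(stats::sd(init[, , , k]), 0)
  expect_equal(init[1, 1, 1, 2], log(1))
  expect_equal(init[1, 1, 1, 3], log(20))
  # doubling intensities shifts a_tilde by log 2 only
  ph2 <- ph
  for (ci in seq_along(ph2$series))
    ph2$series[[ci]]$echoes <- lapply(ph2$series[[ci]]$echoes, function(v) 2 * v)
  init2 <- initialize_maps(ph2$series)
  expect_equal(init2[1, 1, 1, 1] - init[1, 1, 1, 1], log(2), tolerance = 1e-12)
  expect_equal(init2[, , , 2:4], init[, , , 2:4])
})

test_that("assembled gradient equals per-voxel terms and finite differences", {
  ph <- make_phantom(dim = c(4, 4, 4), noise = "gaussian", sigma = 3, seed = 3)
  for (ci in seq_along(ph$series)) ph$series[[ci]]$sigma2 <- 9
  maps <- ph$truth
  asm <- assemble(maps, ph$series)

  # per-voxel equivalence through the signal_model path
  v <- 23  # arbitrary voxel
  idx <- arrayInd(v, dim(maps)[1:3])
  rows <- list()
  for (sr in ph$series) for (e in seq_along(sr$echoes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      intensity = sr$echoes[[e]][idx[1], idx[2], idx[3]],
      flip = sr$flip, tr = sr$tr, te = sr$te[e], sigma2 = sr$sigma2,
      mt = sr$mt)
  }
  p <- as_lp(maps[idx[1], idx[2], idx[3], ])
  vt <- voxel_objective_terms(p, do.call(rbind, rows))
  expect_equal(unname(asm$grad[v, ]), unname(vt$gradient), tolerance = 1e-10)
  expect_equal(unname(asm$H[v, , ]), unname(vt$preconditioner),
               tolerance = 1e-10)

  # directional derivative against the objective
  set.seed(603)
  d <- array(rnorm(length(maps)), dim(maps))
  h <- 1e-5
  shift <- function(s) map_stack(unclass(maps) + s * d,
                                 affine = attr(maps, "affine"),
                                 voxel_size = attr(maps, "voxel_size"))
  fd <- (mpmfit:::mpm_objective(shift(h), ph$series) -
           mpmfit:::mpm_objective(shift(-h), ph$series)) / (2 * h)
  expect_equal(sum(asm$grad * matrix(d, ncol = 4)), fd,
               tolerance = 1e-4 * max(abs(fd), 1))
})

test_that("gradient vanishes at the noiseless ground truth", {
  ph <- make_phantom(dim = c(6, 6, 6), noise = "none")
  for (ci in seq_along(ph$series)) ph$series[[ci]]$sigma2 <- 1
  asm <- assemble(ph$truth, ph$series)
  expect_lt(max(abs(asm$grad)), 1e-8)
  expect_equal(asm$nll, 0, tolerance = 1e-16)
})

test_that("PCG matches block solves without prior and dense solves with", {
  set.seed(604)
  d <- c(6, 6, 6); N <- prod(d); K <- 4
  cfg <- jtv_config(lambda = c(2, 1, 0.5, 1))
  H <- array(0, c(N, K, K))
  for (n in seq_len(N)) {
    A <- matrix(rnorm(K * K), K)
    H[n, , ] <- crossprod(A) + diag(K) * 0.5
  }
  rhs <- matrix(rnorm(N * K), N, K)
  # no prior: per-voxel block solves
  s0 <- pcg_solve(H, rhs)
  expect_equal(mpmfit:::block_mult(H, s0$x), rhs, tolerance = 1e-6)

  w <- array(exp(rnorm(N, 0, 0.3)), d)
  sol <- pcg_solve(H, rhs, w, cfg, d, max_iter = 400, tol = 1e-10)
  # dense oracle
  Hd <- matrix(0, N * K, N * K)
  for (i in 1:K) for (j in 1:K)
    Hd[cbind(rep(seq_len(N), 1) + (i - 1) * N,
             seq_len(N) + (j - 1) * N)] <- H[, i, j]
  Ld <- dense_operator(function(e) {
    m <- array(e, c(d, K))
    as.vector(apply_regulariser(m, w, cfg))
  }, N * K)
  xd <- solve(Hd + Ld, as.vector(rhs))
  expect_lt(max(abs(as.vector(sol$x) - xd)) / max(abs(xd)), 1e-4)
})

test_that("CG energy is non-increasing over iterations", {
  set.seed(605)
  d <- c(5, 5, 5); N <- prod(d); K <- 4
  cfg <- jtv_config(lambda = 1)
  H <- array(0, c(N, K, K))
  for (n in seq_len(N)) {
    A <- matrix(rnorm(K * K), K)
    H[n, , ] <- crossprod(A) + diag(K)
  }
  rhs <- matrix(rnorm(N * K), N, K)
  w <- array(1, d)
  energy <- function(x) {
    xa <- array(x, c(d, K))
    0.5 * sum(x * mpmfit:::block_mult(H, x)) +
      0.5 * sum(xa * apply_regulariser(xa, w, cfg)) - sum(x * rhs)
  }
  es <- vapply(1:12, function(i)
    energy(pcg_solve(H, rhs, w, cfg, d, max_iter = i, tol = 0)$x),
    numeric(1))
  expect_true(all(diff(es) <= 1e-8 * abs(es[1])))
})

test_that("ML fit on a noiseless phantom recovers every map", {
  ph <- make_phantom(dim = c(8, 8, 8), noise = "none")
  for (ci in seq_along(ph$series)) ph$series[[ci]]$sigma2 <- 9
  fit <- mpm_fit(ph$series, mode = "ml",
                 control = mpm_control(ml_max_iter = 60, ml_tol = 1e-12))
  for (k in 1:4)
    expect_lt(max(abs(fit$maps[, , , k] - ph$truth[, , , k])), 1e-3)
  expect_true(all(diff(fit$trace$objective) <= 1e-10))
})

test_that("with identity affines and no prior the fit matches fit_voxel", {
  ph <- make_phantom(dim = c(4, 4, 4), noise = "gaussian", sigma = 3, seed = 9)
  for (ci in seq_along(ph$series)) ph$series[[ci]]$sigma2 <- 9
  init <- initialize_maps(ph$series)
  fit <- mpm_fit(ph$series, mode = "ml", init = init,
                 control = mpm_control(ml_max_iter = 200, ml_tol = 0))
  v <- 37
  idx <- arrayInd(v, dim(init)[1:3])
  rows <- list()
  for (sr in ph$series) for (e in seq_along(sr$echoes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      intensity = sr$echoes[[e]][idx[1], idx[2], idx[3]],
      flip = sr$flip, tr = sr$tr, te = sr$te[e], sigma2 = sr$sigma2,
      mt = sr$mt)
  }
  f1 <- fit_voxel(do.call(rbind, rows), init = as_lp(init[idx[1], idx[2],
                                                          idx[3], ]),
                  method = "proposed", max_iter = 200)
  expect_equal(unname(fit$maps[idx[1], idx[2], idx[3], ]),
               unname(unclass(f1$params)), tolerance = 1e-6)
})

test_that("MAP fit decreases the true MAP objective and returns weights", {
  ph <- make_phantom(dim = c(8, 8, 8), noise = "gaussian", sigma = 3, seed = 11)
  fit <- mpm_fit(ph$series, mode = "map", lambda = 10,
                 control = mpm_control(max_irls = 4))
  tr <- fit$trace[fit$trace$phase == "irls", ]
  expect_true(all(tr$gain >= -1e-8 * abs(tr$objective[1])))
  expect_true(all(fit$weights > 0))
  expect_equal(dim(fit$weights), c(8, 8, 8))
})

test_that("the ESTATICS likelihood runs through the same solver", {
  ph <- make_phantom(dim = c(6, 6, 6), noise = "gaussian", sigma = 2, seed = 13)
  for (ci in seq_along(ph$series)) ph$series[[ci]]$sigma2 <- 4
  fit <- mpm_fit(ph$series, mode = "map", model = "estatics",
                 lambda = c(1000, 1000, 1000, 0.1),
                 control = mpm_control(max_irls = 3))
  expect_equal(dim(fit$maps)[4L], 4L)  # 3 intercepts + shared log R2*
  tr <- fit$trace[fit$trace$phase == "irls", ]
  expect_true(all(tr$gain >= -1e-8 * abs(tr$objective[1])))
  # r2 map should sit in a plausible range in the interior
  r2 <- exp(fit$maps[, , , 4])
  expect_true(stats::median(r2) > 0.5 && stats::median(r2) < 50)
})

test_that("mask and B1 inputs are honoured", {
  ph <- make_phantom(dim = c(6, 6, 6), noise = "none")
  for (ci in seq_along(ph$series)) ph$series[[ci]]$sigma2 <- 1
  mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  asm <- assemble(ph$truth, ph$series, mask = mask)
  expect_lt(max(abs(asm$grad)), 1e-8)
  # a wrong B1 map must break the fit at truth (nonzero gradient)
  b1 <- array(0.9, c(6, 6, 6))
  asm2 <- assemble(ph$truth, ph$series, b1 = b1)
  expect_gt(max(abs(asm2$grad)), 1e-3)
})
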