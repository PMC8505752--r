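# SPGR forward model: closed-form limits, finite-difference oracles and the
# structure of the residual-loaded preconditioner.

test_that("signal reduces to its closed-form limits", {
  # full saturation recovery: a = 1, delta = 0, alpha = pi/2, r1*tr >> 1
  p <- log_params(0, log(50), 0, 0)
  acq <- acq_params(pi / 2, 1, 0, 1, mt = FALSE)
  expect_equal(spgr_signal(p, acq), 1, tolerance = 1e-12)

  # exponential decay factor: with r2 = 1/s, te = ln 2 the ratio is 1/2
  p <- log_params(0.4, -0.1, log(1), 0.3)
  acq0 <- acq_params(0.3, 0.02, 0, 1, mt = TRUE)
  acq1 <- acq_params(0.3, 0.02, log(2), 1, mt = TRUE)
  expect_equal(spgr_signal(p, acq1) / spgr_signal(p, acq0), 0.5,
               tolerance = 1e-12)

  # zero flip angle gives zero signal, no error
  expect_equal(spgr_signal(p, acq_params(0, 0.02, 0.01, 1, TRUE)), 0)

  # delta = 0, te = 0 closed form (Ernst equation)
  a <- 2; r1 <- 1.3; tr <- 0.05; al <- 0.3
  p <- log_params(log(a), log(r1), 0, 0)
  E <- exp(-r1 * tr)
  expect_equal(spgr_signal(p, acq_params(al, tr, 0, 1, FALSE)),
               a * sin(al) * (1 - E) / (1 - cos(al) * E), tolerance = 1e-14)
})

test_that("Ernst angle maximises the signal (dense grid oracle)", {
  r1 <- 0.8; tr <- 0.03
  p <- log_params(0.7, log(r1), log(15), 0)
  alphas <- seq(1e-3, pi / 2, length.out = 20001)
  s <- vapply(alphas,
              function(a) spgr_signal(p, acq_params(a, tr, 0.002, 1, FALSE)),
              numeric(1))
  a_best <- alphas[which.max(s)]
  expect_equal(cos(a_best), exp(-r1 * tr), tolerance = 1e-4)
})

test_that("gradient components have their stated structure", {
  set.seed(101)
  for (i in 1:20) {
    p <- rand_log_params()
    acq <- rand_acq(mt = i %% 2 == 0)
    g <- spgr_gradient(p, acq)
    s <- spgr_signal(p, acq)
    expect_identical(unname(g[1]), s)                   # ds/da_tilde = s
    r2 <- exp(p[["r2_tilde"]])
    expect_equal(unname(g[3]), -acq$te * r2 * s, tolerance = 1e-12)
    if (!acq$mt) expect_identical(unname(g[4]), 0)
  }
  # te = 0 kills the r2 component
  g0 <- spgr_gradient(log_params(1, 0, 1, 0), acq_params(0.4, 0.1, 0, 1, TRUE))
  expect_identical(unname(g0[3]), 0)
})

test_that("gradient matches central finite differences on random draws", {
  set.seed(102)
  worst <- 0
  for (i in 1:100) {
    p <- rand_log_params()
    acq <- rand_acq(mt = i %% 3 == 0)
    g <- spgr_gradient(p, acq)
    gfd <- fd_gradient(function(x) spgr_signal(as_lp(x), acq), unclass(p))
    if (!acq$mt) gfd[4] <- 0
    worst <- max(worst, max(abs(g - gfd)) / max(abs(gfd), 1e-10))
  }
  expect_lt(worst, 1e-5)
})

test_that("Hessian diagonal matches second-order central differences", {
  set.seed(103)
  worst <- 0
  for (i in 1:100) {
    p <- rand_log_params()
    acq <- rand_acq(mt = i %% 3 == 0)
    hd <- spgr_hessian_diag(p, acq)
    h <- 1e-4
    hfd <- vapply(1:4, function(k) {
      xp <- unclass(p); xm <- unclass(p)
      xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      (spgr_signal(as_lp(xp), acq) - 2 * spgr_signal(p, acq) +
         spgr_signal(as_lp(xm), acq)) / h^2
    }, numeric(1))
    if (!acq$mt) hfd[4] <- 0
    worst <- max(worst, max(abs(hd - hfd)) / max(abs(hfd), 1e-8))
  }
  expect_lt(worst, 1e-4)
})

test_that("Hessian diagonal identities hold", {
  set.seed(104)
  p <- rand_log_params()
  acq <- rand_acq(TRUE)
  hd <- spgr_hessian_diag(p, acq)
  g <- spgr_gradient(p, acq)
  expect_identical(unname(hd[1]), unname(g[1]))   # d2s/da2 = ds/da
  r2 <- exp(p[["r2_tilde"]])
  expect_equal(unname(hd[3]), (1 - acq$te * r2) * unname(g[3]),
               tolerance = 1e-12)
  # te = 1/r2 zeroes the r2 second derivative
  acq0 <- acq_params(acq$flip, acq$tr, 1 / r2, acq$sigma2, acq$mt)
  expect_equal(unname(spgr_hessian_diag(p, acq0)[3]), 0, tolerance = 1e-20)
})

test_that("full Hessian matches finite differences of the gradient", {
  set.seed(105)
  worst <- 0
  for (i in 1:50) {
    p <- rand_log_params()
    acq <- rand_acq(TRUE)
    H <- spgr_hessian(p, acq)
    h <- 1e-5
    Hfd <- sapply(1:4, function(k) {
      xp <- unclass(p); xm <- unclass(p)
      xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      (spgr_gradient(as_lp(xp), acq) - spgr_gradient(as_lp(xm), acq)) / (2 * h)
    })
    worst <- max(worst, max(abs(H - Hfd)) / max(abs(H)))
  }
  expect_lt(worst, 1e-5)
})

test_that("preconditioner recovers Gauss-Newton at zero residual and is PSD", {
  set.seed(106)
  p <- rand_log_params()
  obs <- make_voxel_obs(p)  # noiseless: residuals are exactly 0
  vt <- voxel_objective_terms(p, obs)
  G <- t(sapply(seq_len(nrow(obs)), function(i) {
    acq <- acq_params(obs$flip[i], obs$tr[i], obs$te[i], obs$sigma2[i],
                      obs$mt[i])
    spgr_gradient(p, acq)
  }))
  gn <- crossprod(G / sqrt(obs$sigma2))
  expect_equal(unname(vt$preconditioner), unname(gn), tolerance = 1e-12)
  expect_equal(vt$nll, 0, tolerance = 1e-18)

  # with residuals: P_tilde - GN is diagonal and nonnegative (Loewner order)
  for (i in 1:50) {
    p2 <- rand_log_params()
    obs2 <- obs
    obs2$intensity <- obs$intensity + rnorm(nrow(obs))
    vt2 <- voxel_objective_terms(p2, obs2)
    Gm <- t(sapply(seq_len(nrow(obs2)), function(j) {
      acq <- acq_params(obs2$flip[j], obs2$tr[j], obs2$te[j], 1, obs2$mt[j])
      spgr_gradient(p2, acq)
    }))
    gn2 <- crossprod(Gm / sqrt(obs2$sigma2))
    D <- vt2$preconditioner - gn2
    expect_lt(max(abs(D - diag(diag(D)))), 1e-10 * max(abs(D), 1))
    expect_true(all(diag(D) >= -1e-12))
    expect_gt(min(eigen(vt2$preconditioner, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
  }
})

test_that("rowsum loading dominates the diagonal loading", {
  set.seed(107)
  p <- rand_log_params()
  obs <- make_voxel_obs(p, noise_sd = 1)
  d1 <- voxel_objective_terms(p, obs, loading = "diag")$preconditioner
  d2 <- voxel_objective_terms(p, obs, loading = "rowsum")$preconditioner
  expect_true(all(diag(d2) >= diag(d1) - 1e-12))
})

test_that("scalar r2-only preconditioner has the toy-problem structure", {
  # single observation, only r2_tilde active: p_tilde = g^2 + |res| |h|
  p <- log_params(0, 0, 0.3, 0)
  acq <- acq_params(pi / 2, 10, 1, 1, FALSE)  # saturated: s = exp(-r2 te)
  x <- 0.4
  obs <- data.frame(intensity = x, flip = acq$flip, tr = acq$tr,
                    te = acq$te, sigma2 = 1, mt = FALSE)
  vt <- voxel_objective_terms(p, obs)
  s <- spgr_signal(p, acq)
  g3 <- unname(spgr_gradient(p, acq)[3])
  h3 <- unname(spgr_hessian_diag(p, acq)[3])
  expect_equal(vt$preconditioner[3, 3], g3^2 + abs(s - x) * abs(h3),
               tolerance = 1e-12)
})

test_that("domain errors are raised", {
  p <- log_params(0, 0, 0, 0)
  expect_error(log_params(Inf, 0, 0, 0), "finite")
  expect_error(acq_params(0.1, -1, 0.01), "tr")
  expect_error(acq_params(0.1, 1, 0.01, sigma2 = 0), "sigma2")
  expect_error(voxel_objective_terms(p, data.frame()), "observation")
  obs <- make_voxel_obs(p)
  obs$sigma2[3] <- -1
  expect_error(voxel_objective_terms(p, obs), "sigma2")
})
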