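# Newton stepping, toy problems, the monotone-step diagnostic and the
# per-voxel fitters.

test_that("newton_step solves the loaded system", {
  expect_equal(newton_step(rep(0, 4), diag(4)), rep(0, 4))
  g <- c(1, -2, 3, 0.5)
  expect_equal(newton_step(g, diag(4)), g, tolerance = 1e-9)
  set.seed(201)
  for (i in 1:20) {
    A <- matrix(rnorm(16), 4)
    P <- crossprod(A) + diag(4) * 0.1
    g <- rnorm(4)
    s <- newton_step(g, P)
    expect_lt(max(abs(P %*% s - g)), 1e-10 * max(abs(g)))
  }
  expect_error(newton_step(c(1, 1), matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("toy closed forms match their derivation", {
  tp <- toy_problem("exp_ls", x = 1)
  d <- toy_derivatives(tp, 0)
  expect_equal(d$objective, 0)
  expect_equal(d$gradient, 0)
  expect_equal(d$proposed, d$gn)  # preconditioners agree at zero residual
  expect_equal(d$gn, 1)

  # generic point: g = -(e^-y - x) e^-y, p = e^-2y
  d2 <- toy_derivatives(tp, 1.3)
  expect_equal(d2$gradient, -(exp(-1.3) - 1) * exp(-1.3), tolerance = 1e-14)
  expect_equal(d2$gn, exp(-2.6), tolerance = 1e-14)
  expect_equal(d2$proposed, exp(-2.6) + abs(exp(-1.3) - 1) * exp(-1.3),
               tolerance = 1e-14)

  # nested kind: derivatives agree with numerical differentiation
  tp2 <- toy_problem("nested_exp_ls", x = 0.4)
  for (y in c(-2, -0.5, 0.7, 2)) {
    d3 <- toy_derivatives(tp2, y)
    gn <- fd_gradient(function(v) toy_derivatives(tp2, v[1])$objective, y)
    expect_equal(d3$gradient, gn, tolerance = 1e-6)
    hn <- fd_gradient(function(v) toy_derivatives(tp2, v[1])$gradient, y,
                      h = 1e-5)
    expect_equal(d3$hessian, hn, tolerance = 1e-5)
  }
})

test_that("proposed preconditioner converges monotonically on exp_ls", {
  tp <- toy_problem("exp_ls", x = exp(-2))
  expect_equal(toy_optimum(tp), 2)
  for (y0 in c(-3, 7)) {  # non-convex and convex side
    f <- toy_fit(tp, y0, "proposed", max_iter = 200)
    expect_lt(abs(f$y - 2), 1e-6)
    expect_true(all(diff(f$trace$objective) <= 1e-12))
  }
})

test_that("step condition holds for proposed, fails for Gauss-Newton", {
  for (kind in c("exp_ls", "nested_exp_ls")) {
    x <- if (kind == "exp_ls") exp(-1.5) else 0.3
    tp <- toy_problem(kind, x = x)
    ystar <- toy_optimum(tp)
    grid <- seq(ystar - 6, ystar + 6, length.out = 1201)
    dprop <- check_step_condition(tp, grid, "proposed")
    expect_true(all(dprop$ok))
    # the optimum itself: ratio 0 <= 0
    d0 <- check_step_condition(tp, ystar, "proposed")
    expect_equal(d0$ratio, 0)
    dgn <- check_step_condition(tp, grid, "gn")
    expect_false(all(dgn$ok))
  }
  # exp_ls GN ratio derivative is -x e^y: exceeds 1 beyond y* (Eq-level fact)
  tp <- toy_problem("exp_ls", x = 0.5)
  grid <- seq(toy_optimum(tp) + 0.5, toy_optimum(tp) + 6, length.out = 200)
  expect_false(all(check_step_condition(tp, grid, "gn")$ok))
})

test_that("2-D toy problems: analytic optimum and proposed convergence", {
  tp <- toy_problem("exp2d", x = c(0.7, 0.2), t = c(1, 3))
  opt <- toy_optimum(tp)
  d <- toy_derivatives(tp, opt)
  expect_lt(max(abs(d$gradient)), 1e-12)
  nopt <- stats::optim(opt + 0.1, function(v) toy_derivatives(tp, v)$objective,
                       method = "BFGS")$par
  expect_equal(unname(opt), unname(nopt), tolerance = 1e-4)

  tp2 <- toy_problem("nested_exp2d", x = c(0.7, 0.2), t = c(1, 3))
  opt2 <- toy_optimum(tp2)
  f <- toy_fit(tp2, opt2 + c(1.5, -1), "proposed", max_iter = 500)
  expect_lt(sqrt(sum((f$y - opt2)^2)), 1e-6)
  expect_true(all(diff(f$trace$objective) <= 1e-10))
  f2 <- toy_fit(tp2, opt2 + c(1.5, -1), "proposed_rowsum", max_iter = 500)
  expect_lt(sqrt(sum((f2$y - opt2)^2)), 1e-6)
})

test_that("fit_voxel recovers noiseless parameters and is monotone", {
  set.seed(202)
  p <- log_params(0.5, -0.3, 0.8, -0.6)
  obs <- make_voxel_obs(p)
  f <- fit_voxel(obs, method = "proposed", max_iter = 500)
  expect_lt(max(abs(unclass(f$params) - unclass(p))), 1e-4)
  expect_true(all(f$trace$gain[-1] >= -1e-12 * abs(f$trace$objective[1])))
  expect_equal(f$objective, 0, tolerance = 1e-12)
})

test_that("all methods decrease the objective on noisy voxels", {
  set.seed(203)
  p <- log_params(0.5, -0.3, 0.8, -0.6)
  obs <- make_voxel_obs(p, noise_sd = 0.05)
  for (method in c("proposed", "proposed_rowsum", "gauss_newton_linesearch",
                   "levenberg_marquardt")) {
    f <- fit_voxel(obs, method = method, max_iter = 50)
    expect_true(all(diff(f$trace$objective) <= 1e-12),
                info = method)
    expect_lt(f$objective, f$trace$objective[1])
  }
})

test_that("non-log bases reach the same noiseless optimum", {
  p <- log_params(0.5, -0.3, 0.8, -0.6)
  obs <- make_voxel_obs(p)
  for (basis in c("rate", "time")) {
    f <- fit_voxel(obs, basis = basis, max_iter = 2000)
    expect_lt(max(abs(unclass(f$params) - unclass(p))), 1e-3)
  }
})

test_that("basis encodings are mutually inverse", {
  set.seed(204)
  Y <- matrix(rnorm(40), 10, 4)
  for (basis in c("log", "rate", "time")) {
    U <- mpmfit:::basis_encode(Y, basis)
    expect_equal(mpmfit:::basis_decode(U, basis), Y, tolerance = 1e-12)
  }
})

test_that("batched engine agrees with single-voxel fits", {
  sim <- simulate_voxels(n_voxels = 5, sigma2 = 1, seed = 42)
  m <- observation_matrices(sim$observations)
  batch <- mpmfit:::fit_voxels_engine(m$intensity, m$flip, m$tr, m$te,
                                      m$sigma2, m$mt, method = "proposed",
                                      max_iter = 50)
  for (v in 1:5) {
    obs <- sim$observations[sim$observations$voxel == v, ]
    f <- fit_voxel(obs, method = "proposed", max_iter = 50)
    expect_equal(unname(unclass(f$params)), unname(batch$params[v, ]),
                 tolerance = 1e-10)
    expect_equal(f$trace$objective, unname(batch$objective[v, ]),
                 tolerance = 1e-10)
  }
})

test_that("gain normalisation and first-passage iteration behave", {
  objs <- c(10, 5, 2, 1, 1)
  g <- normalised_gain(objs)
  expect_equal(sum(g), 1, tolerance = 1e-10)
  expect_true(all(g >= 0))
  it <- iterations_to_tolerance(matrix(objs, 1), tol = 0.2)
  expect_equal(it, 2L)  # first value within 1 + 0.2*9 = 2.8
})
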