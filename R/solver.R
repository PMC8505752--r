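# Full-volume fitting: noise estimation, initialisation, gradient/Hessian
# assembly across contrasts and echoes (with spatial pull/push), the IRLS
# outer loop, safeguarded Newton inner loop and preconditioned conjugate
# gradient solves.

#' Two-class Rician mixture fit of an intensity histogram
#'
#' EM fit of a two-class Rician mixture to magnitude intensities. The class
#' with the lowest mean is taken as background; its scale parameter
#' estimates the thermal noise. Each EM iteration uses the standard
#' fixed-point updates \eqn{\nu \leftarrow \sum\gamma x b / \sum\gamma} and
#' \eqn{\sigma^2 \leftarrow \sum\gamma (x^2 - 2\nu x b + \nu^2)/(2\sum\gamma)}
#' where \eqn{b = I_1(x\nu/\sigma^2)/I_0(x\nu/\sigma^2)}.
#'
#' @param x numeric vector of nonnegative intensities.
#' @param max_iter,tol EM iteration control.
#' @param n_sample deterministic subsample cap (stride subsampling).
#' @return list with `sigma2` (background noise variance), `nu` (class
#'   locations), `sigma2_class`, `prop` (mixing proportions), `bg_mean` and
#'   `fg_mean` (class intensity means).
#' @export
rician_mixture <- function(x, max_iter = 200, tol = 1e-8, n_sample = 1e5) {
  x <- as.vector(x)
  x <- x[is.finite(x)]
  x <- abs(x)
  if (length(unique(round(x, 10))) < 3L)
    stop("degenerate intensity histogram", call. = FALSE)
  if (length(x) > n_sample) {
    stride <- ceiling(length(x) / n_sample)
    x <- x[seq(1L, length(x), by = stride)]
  }
  x <- pmax(x, 1e-10 * max(x))
  # moment-based initialisation: split at the overall mean
  thr <- mean(x)
  nu <- c(mean(x[x <= thr]) / 2, mean(x[x > thr]))
  s2 <- rep(stats::var(x) / 4, 2) + 1e-12
  pr <- c(mean(x <= thr), mean(x > thr))

  ldrice <- function(x, nu, s2) {
    z <- x * nu / s2
    log(x) - log(s2) - (x^2 + nu^2) / (2 * s2) + z +
      log(besselI(z, 0, expon.scaled = TRUE))
  }
  bratio <- function(z)
    besselI(z, 1, expon.scaled = TRUE) / besselI(z, 0, expon.scaled = TRUE)

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- cbind(log(pr[1]) + ldrice(x, nu[1], s2[1]),
                log(pr[2]) + ldrice(x, nu[2], s2[2]))
    mx <- pmax(lp[, 1], lp[, 2])
    lse <- mx + log(exp(lp[, 1] - mx) + exp(lp[, 2] - mx))
    ll <- sum(lse)
    g1 <- exp(lp[, 1] - lse)
    g2 <- 1 - g1
    for (k in 1:2) {
      g <- if (k == 1) g1 else g2
      sg <- sum(g) + 1e-12
      b <- bratio(x * nu[k] / s2[k])
      nu_new <- sum(g * x * b) / sg
      s2[k] <- max(sum(g * (x^2 - 2 * nu_new * x * b + nu_new^2)) / (2 * sg),
                   1e-12 * mean(x)^2 + 1e-300)
      nu[k] <- nu_new
      pr[k] <- sg / length(x)
    }
    pr <- pr / sum(pr)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  bg <- which.min(nu)
  fg <- 3L - bg
  # class intensity means (Rician mean via the Laguerre-free large-z
  # approximation is unnecessary here; use responsibility-weighted means)
  m1 <- sum(g1 * x) / (sum(g1) + 1e-12)
  m2 <- sum(g2 * x) / (sum(g2) + 1e-12)
  mns <- c(m1, m2)
  list(sigma2 = s2[bg], nu = nu, sigma2_class = s2, prop = pr,
       bg_mean = mns[bg], fg_mean = mns[fg])
}

#' Estimate the thermal noise variance of a contrast series
#'
#' Fits a two-class Rician mixture to every echo volume, takes the
#' background-class variance of each, and combines them across echoes with
#' the geometric mean. Also returns the foreground (non-background) class
#' mean of each echo, used to initialise the parameter maps.
#'
#' @param series a [contrast_series()].
#' @return list with `sigma2` (series noise variance, geometric mean across
#'   echoes), `per_echo` (data frame with `echo`, `sigma2`, `bg_mean`,
#'   `fg_mean`).
#' @export
estimate_noise <- function(series) {
  fits <- lapply(series$echoes, rician_mixture)
  s2 <- vapply(fits, `[[`, numeric(1), "sigma2")
  per <- data.frame(echo = seq_along(fits), sigma2 = s2,
                    bg_mean = vapply(fits, `[[`, numeric(1), "bg_mean"),
                    fg_mean = vapply(fits, `[[`, numeric(1), "fg_mean"))
  list(sigma2 = exp(mean(log(s2))), per_echo = per)
}

#' Constant initial parameter maps
#'
#' Spatially constant initialisation: the log proton-density scaling from
#' the mean foreground intensity of the lowest-flip non-MT series (first
#' echo), and fixed physiological constants for the rest
#' (R1 = 1/s, R2* = 20/s, MTsat = 0.01). Deterministic; doubling all
#' intensities shifts the `a_tilde` plane by log 2 and nothing else.
#'
#' @param series list of [contrast_series()].
#' @param model `"spgr"` (4 channels) or `"estatics"` (one log-intercept
#'   channel per contrast plus a shared log R2*).
#' @param fg_mean optional precomputed foreground means (one per series,
#'   e.g. from [estimate_noise()]); defaults to the mean intensity above
#'   the volume mean of the first echo.
#' @return a [map_stack()] of constant planes.
#' @export
initialize_maps <- function(series, model = c("spgr", "estatics"),
                            fg_mean = NULL) {
  model <- match.arg(model)
  dims <- series[[1L]]$dim
  C <- length(series)
  if (is.null(fg_mean)) {
    fg_mean <- vapply(series, function(s) {
      v <- s$echoes[[1L]]
      mean(v[v > mean(v)])
    }, numeric(1))
  }
  fg_mean <- pmax(fg_mean, 1e-12)
  if (model == "spgr") {
    flips <- vapply(series, `[[`, numeric(1), "flip")
    mts <- vapply(series, function(s) s$mt, logical(1))
    cand <- which(!mts)
    if (!length(cand)) cand <- seq_len(C)
    ref <- cand[which.min(flips[cand])]
    planes <- c(log(fg_mean[ref]), log(1), log(20), logit(0.01))
    K <- 4L
  } else {
    planes <- c(log(fg_mean), log(20))
    K <- C + 1L
  }
  maps <- array(0, c(dims, K))
  for (k in seq_len(K)) maps[, , , k] <- planes[k]
  map_stack(maps, affine = series[[1L]]$affine,
            voxel_size = series[[1L]]$voxel_size,
            names = if (model == "spgr") NULL
                    else c(paste0("intercept", seq_len(C)), "r2_tilde"))
}

# Per-volume signal terms for the two supported forward models, evaluated
# on pulled maps (matrix Ym of M x K values). Returns s, per-channel signal
# gradients and Hessian diagonals plus the channel index sets that are
# active for this volume.
model_terms <- function(model, Ym, flip, tr, te, mt, contrast, K) {
  if (model == "spgr") {
    k <- spgr_kernel(Ym[, 1], Ym[, 2], Ym[, 3], Ym[, 4], flip, tr, te, mt,
                     hessian = TRUE)
    list(s = k$s,
         g = list(k$g_a, k$g_r1, k$g_r2, k$g_dt),
         h = list(k$h_aa, k$h_r1r1, k$h_r2r2, k$h_dtdt),
         active = if (mt) 1:4 else 1:3)
  } else {
    b <- Ym[, contrast]
    r2 <- exp(pmin(Ym[, K], 700))
    x2 <- pmin(r2 * te, 700)
    s <- exp(pmin(b, 700) - x2)
    g_r2 <- -x2 * s
    g <- vector("list", K); h <- vector("list", K)
    g[[contrast]] <- s;    h[[contrast]] <- s
    g[[K]] <- g_r2;        h[[K]] <- (1 - x2) * g_r2
    list(s = s, g = g, h = h, active = c(contrast, K))
  }
}

#' Assemble objective, gradient and approximate Hessian over all volumes
#'
#' Evaluates the Gaussian negative log-likelihood of all echo volumes at
#' the current maps, together with its gradient and the block-diagonal
#' approximate Hessian (Gauss-Newton plus absolute-residual diagonal
#' loading), accumulated in reconstruction space. When the acquisition
#' grids differ from the reconstruction grid, maps are pulled to each
#' acquisition space, the per-voxel terms computed there, and pushed back
#' through the adjoint; the pushed block-diagonal Hessian majorises the
#' full resliced Hessian. When a weight field `w` is given, the quadratic
#' IRLS prior is added: `L y` to the gradient and `(1/2) y' L y` to the
#' objective (the Hessian blocks stay likelihood-only; the prior enters the
#' linear system and preconditioner separately).
#'
#' @param maps a [map_stack()] (current estimate).
#' @param series list of [contrast_series()] with `sigma2` set.
#' @param w optional 3-D IRLS weight field.
#' @param cfg a [jtv_config()] (required with `w`).
#' @param model `"spgr"` or `"estatics"`.
#' @param mask optional logical 3-D array restricting the likelihood.
#' @param b1 optional 3-D transmit-efficiency field scaling flip angles.
#' @return list with `nll`, `prior`, `objective` (their sum), `grad`
#'   (`N x K` matrix) and `H` (`N x K x K` block field).
#' @export
assemble <- function(maps, series, w = NULL, cfg = NULL,
                     model = c("spgr", "estatics"), mask = NULL, b1 = NULL) {
  model <- match.arg(model)
  dims <- dim(maps)[1:3]
  K <- dim(maps)[4L]
  N <- prod(dims)
  grad <- matrix(0, N, K)
  H <- array(0, c(N, K, K))
  nll <- 0
  for (ci in seq_along(series)) {
    sr <- series[[ci]]
    if (is.null(sr$sigma2)) stop("series noise variance not set", call. = FALSE)
    op <- projection_operator(dims, attr(maps, "affine"), sr$dim, sr$affine)
    Ym <- pull(unclass(maps), op)
    dim(Ym) <- c(prod(sr$dim), K)
    mloc <- if (is.null(mask)) NULL else {
      mm <- pull(mask * 1, op)
      as.vector(mm) > 0.5
    }
    b1loc <- if (is.null(b1)) 1 else as.vector(pull(b1, op))
    iv <- 1 / sr$sigma2
    for (e in seq_along(sr$echoes)) {
      tm <- model_terms(model, Ym, sr$flip * b1loc, sr$tr, sr$te[e], sr$mt,
                        ci, K)
      r <- tm$s - as.vector(sr$echoes[[e]])
      if (!is.null(mloc)) r[!mloc] <- 0
      nll <- nll + sum(r^2) * iv / 2
      act <- tm$active
      gfields <- vector("list", K)
      for (i in act) gfields[[i]] <- r * iv * tm$g[[i]]
      hfields <- vector("list", K * K)
      ar <- abs(r) * iv
      for (i in act) for (j in act[act >= i]) {
        v <- tm$g[[i]] * tm$g[[j]] * iv
        if (i == j) v <- v + ar * abs(tm$h[[i]])
        hfields[[(i - 1) * K + j]] <- v
      }
      # push back to reconstruction space and accumulate
      for (i in act) {
        grad[, i] <- grad[, i] +
          as.vector(push(array(gfields[[i]], sr$dim), op))
      }
      for (i in act) for (j in act[act >= i]) {
        v <- as.vector(push(array(hfields[[(i - 1) * K + j]], sr$dim), op))
        H[, i, j] <- H[, i, j] + v
        if (i != j) H[, j, i] <- H[, j, i] + v
      }
    }
  }
  prior <- 0
  if (!is.null(w)) {
    Ly <- apply_regulariser(unclass(maps), w, cfg)
    dim(Ly) <- c(N, K)
    ym <- unclass(maps); dim(ym) <- c(N, K)
    prior <- sum(ym * Ly) / 2
    grad <- grad + Ly
  }
  list(nll = nll, prior = prior, objective = nll + prior, grad = grad, H = H)
}

# Objective only (for line-search safeguards); same conventions as assemble.
mpm_objective <- function(maps, series, w = NULL, cfg = NULL,
                          model = "spgr", mask = NULL, b1 = NULL) {
  dims <- dim(maps)[1:3]
  K <- dim(maps)[4L]
  nll <- 0
  for (ci in seq_along(series)) {
    sr <- series[[ci]]
    op <- projection_operator(dims, attr(maps, "affine"), sr$dim, sr$affine)
    Ym <- pull(unclass(maps), op)
    dim(Ym) <- c(prod(sr$dim), K)
    mloc <- if (is.null(mask)) NULL else as.vector(pull(mask * 1, op)) > 0.5
    b1loc <- if (is.null(b1)) 1 else as.vector(pull(b1, op))
    iv <- 1 / sr$sigma2
    for (e in seq_along(sr$echoes)) {
      tm <- model_terms(model, Ym, sr$flip * b1loc, sr$tr, sr$te[e], sr$mt,
                        ci, K)
      r <- tm$s - as.vector(sr$echoes[[e]])
      if (!is.null(mloc)) r[!mloc] <- 0
      nll <- nll + sum(r^2) * iv / 2
    }
  }
  prior <- 0
  if (!is.null(w)) {
    Ly <- apply_regulariser(unclass(maps), w, cfg)
    ym <- unclass(maps); dim(ym) <- dim(Ly)
    prior <- sum(ym * Ly) / 2
  }
  nll + prior
}

#' Preconditioned conjugate gradient solve of the Newton system
#'
#' Approximately solves `(H + L) delta = rhs`, where `H` is the per-voxel
#' block-diagonal approximate Hessian and `L = lambda_k G' W G` the
#' quadratic prior operator, by conjugate gradient preconditioned with
#' `H + diag(L)` (per-voxel `K x K` blocks plus the exact regulariser
#' diagonal; Jacobi-type preconditioning). With `w = NULL` (no prior) the
#' preconditioner equals the operator and the solve is exact in one
#' application.
#'
#' @param H `N x K x K` block field.
#' @param rhs `N x K` right-hand side.
#' @param w optional IRLS weight field (3-D array).
#' @param cfg a [jtv_config()] (needed with `w`).
#' @param dims grid dimensions.
#' @param max_iter,tol CG iteration cap and relative residual tolerance.
#' @return list with `x` (`N x K`), `iterations`, `rel_residual`.
#' @export
pcg_solve <- function(H, rhs, w = NULL, cfg = NULL, dims = NULL,
                      max_iter = 32, tol = 1e-3) {
  K <- dim(H)[3L]
  if (is.null(w)) {
    x <- block_solve(H, rhs)
    return(list(x = x, iterations = 0L, rel_residual = 0))
  }
  stopifnot(!is.null(dims), !is.null(cfg))
  N <- dim(H)[1L]
  rd <- regulariser_diagonal(w, cfg, K)
  dim(rd) <- c(N, K)
  M <- H
  for (k in seq_len(K)) M[, k, k] <- M[, k, k] + rd[, k]
  Lfac <- block_chol(M)
  Aop <- function(x) {
    xa <- x; dim(xa) <- c(dims, K)
    lv <- apply_regulariser(xa, w, cfg)
    dim(lv) <- c(N, K)
    block_mult(H, x) + lv
  }
  x <- matrix(0, N, K)
  r <- rhs
  b_norm <- sqrt(sum(r^2)) + 1e-300
  z <- block_chol_solve(Lfac, r)
  p <- z
  rz <- sum(r * z)
  it_done <- 0L
  for (it in seq_len(max_iter)) {
    Ap <- Aop(p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) break
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    it_done <- it
    if (sqrt(sum(r^2)) / b_norm < tol) break
    z <- block_chol_solve(Lfac, r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    p <- z + beta * p
    rz <- rz_new
  }
  list(x = x, iterations = it_done,
       rel_residual = sqrt(sum(r^2)) / b_norm)
}

#' Iteration control for [mpm_fit()]
#'
#' Default schedule: 10 IRLS iterations with 5 inner
#' Newton iterations and 32 conjugate-gradient iterations per Newton step;
#' early-stopping tolerances 1e-5 (IRLS), 1e-5 (Newton) and 1e-3 (CG). The
#' maximum-likelihood path has no IRLS loop and runs up to `ml_max_iter`
#' Newton iterations at tolerance `ml_tol`.
#'
#' @param max_irls,max_newton,max_cg iteration caps.
#' @param tol_irls,tol_newton,tol_cg relative gain / residual tolerances.
#' @param ml_max_iter,ml_tol Newton cap and tolerance in ML mode.
#' @param max_halving step halvings allowed by the monotonicity safeguard.
#' @return list of control parameters.
#' @export
mpm_control <- function(max_irls = 10, max_newton = 5, max_cg = 32,
                        tol_irls = 1e-5, tol_newton = 1e-5, tol_cg = 1e-3,
                        ml_max_iter = 100, ml_tol = 1e-9, max_halving = 5) {
  list(max_irls = max_irls, max_newton = max_newton, max_cg = max_cg,
       tol_irls = tol_irls, tol_newton = tol_newton, tol_cg = tol_cg,
       ml_max_iter = ml_max_iter, ml_tol = ml_tol,
       max_halving = max_halving)
}

#' Fit quantitative parameter maps to multi-echo VFA series
#'
#' Full-volume maximum-likelihood (`mode = "ml"`) or joint-total-variation
#' regularised maximum-a-posteriori (`mode = "map"`) fit of the log-encoded
#' parameter maps. MAP mode alternates closed-form IRLS weight updates with
#' safeguarded Newton steps whose linear systems are solved by
#' preconditioned conjugate gradient; ML mode runs safeguarded Newton with
#' per-voxel block solves. Although the residual-loaded approximate Hessian
#' is empirically monotone, each step is only accepted if the objective
#' does not increase; otherwise it is halved a few times (counted in the
#' trace).
#'
#' With `model = "estatics"` the same machinery fits one log-intercept per
#' contrast plus a shared log R2* (the regularised variant of the
#' non-linear ESTATICS baseline).
#'
#' @param series list of [contrast_series()].
#' @param mode `"ml"` or `"map"`.
#' @param model `"spgr"` or `"estatics"`.
#' @param lambda regularisation factor(s), per channel (MAP mode).
#' @param mask optional logical array restricting the likelihood.
#' @param b1 optional transmit-efficiency (B1+) field scaling flip angles.
#' @param init optional initial [map_stack()].
#' @param control see [mpm_control()].
#' @param verbose print per-iteration objective and gain.
#' @return object of class `mpm_fit`: list with `maps` (fitted
#'   [map_stack()]), `weights` (final IRLS field, MAP mode), `trace`
#'   (data frame), `sigma2` (per series), `H` (final Hessian blocks),
#'   `mode`, `model`, `cfg`, `halvings`.
#' @export
mpm_fit <- function(series, mode = c("ml", "map"),
                    model = c("spgr", "estatics"), lambda = 10,
                    mask = NULL, b1 = NULL, init = NULL,
                    control = mpm_control(), verbose = FALSE) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  for (ci in seq_along(series)) {
    if (is.null(series[[ci]]$sigma2))
      series[[ci]]$sigma2 <- estimate_noise(series[[ci]])$sigma2
  }
  if (length(series) < 2L && model == "spgr")
    warning("R1 is not identifiable from a single contrast", call. = FALSE)
  maps <- if (is.null(init)) initialize_maps(series, model) else init
  dims <- dim(maps)[1:3]
  K <- dim(maps)[4L]
  N <- prod(dims)
  cfg <- jtv_config(lambda = rep_len(lambda, K),
                    voxel_size = attr(maps, "voxel_size"))
  halvings <- 0L
  tr_rows <- list()
  note <- function(phase, iter, obj, gain = NA, cg = NA) {
    tr_rows[[length(tr_rows) + 1L]] <<-
      data.frame(phase = phase, iteration = iter, objective = obj,
                 gain = gain, cg_residual = cg)
    if (verbose)
      message(sprintf("[%s %d] obj = %.8g gain = %.3g", phase, iter, obj,
                      gain))
  }

  newton_pass <- function(maps, w, n_iter, tol) {
    obj <- mpm_objective(maps, series, w, cfg, model, mask, b1)
    obj0 <- obj
    H_last <- NULL
    for (it in seq_len(n_iter)) {
      asm <- assemble(maps, series, w, cfg, model, mask, b1)
      H_last <- asm$H
      obj <- asm$objective
      sol <- pcg_solve(asm$H, asm$grad, w, cfg, dims,
                       max_iter = control$max_cg, tol = control$tol_cg)
      step <- sol$x
      fac <- 1
      for (h in 0:control$max_halving) {
        cand <- unclass(maps) - array(fac * step, c(dims, K))
        cand <- map_stack(cand, affine = attr(maps, "affine"),
                          voxel_size = attr(maps, "voxel_size"),
                          names = attr(maps, "channels"))
        obj_new <- mpm_objective(cand, series, w, cfg, model, mask, b1)
        if (is.finite(obj_new) && obj_new <= obj) break
        fac <- fac / 2
        halvings <<- halvings + 1L
        obj_new <- NA
      }
      if (is.na(obj_new) || obj_new > obj) {
        note(if (is.null(w)) "newton" else "newton-map", it, obj, 0,
             sol$rel_residual)
        break # no improving step found; keep current maps
      }
      gain <- obj - obj_new
      maps <- cand
      obj <- obj_new
      note(if (is.null(w)) "newton" else "newton-map", it, obj, gain,
           sol$rel_residual)
      span <- abs(obj0 - obj) + 1e-300
      if (gain < tol * span) break
    }
    list(maps = maps, obj = obj, H = H_last)
  }

  if (mode == "ml") {
    res <- newton_pass(maps, NULL, control$ml_max_iter, control$ml_tol)
    maps <- res$maps
    out_w <- NULL
    H_final <- res$H
  } else {
    obj_true <- mpm_objective(maps, series, NULL, NULL, model, mask, b1) +
      jtv_energy(unclass(maps), cfg)
    obj0 <- obj_true
    w <- irls_weight_update(unclass(maps), cfg)
    H_final <- NULL
    for (irls in seq_len(control$max_irls)) {
      res <- newton_pass(maps, w, control$max_newton, control$tol_newton)
      maps <- res$maps
      H_final <- res$H
      w <- irls_weight_update(unclass(maps), cfg)
      obj_new <- mpm_objective(maps, series, NULL, NULL, model, mask, b1) +
        jtv_energy(unclass(maps), cfg)
      gain <- obj_true - obj_new
      note("irls", irls, obj_new, gain)
      span <- abs(obj0 - obj_new) + 1e-300
      obj_true <- obj_new
      if (gain < control$tol_irls * span) break
    }
    out_w <- w
  }
  structure(list(maps = maps, weights = out_w,
                 trace = do.call(rbind, tr_rows),
                 sigma2 = vapply(series, `[[`, numeric(1), "sigma2"),
                 H = H_final, mode = mode, model = model, cfg = cfg,
                 halvings = halvings),
            class = "mpm_fit")
}

#' @export
print.mpm_fit <- function(x, ...) {
  cat(sprintf("mpm_fit: %s/%s, final objective %.6g (%d step halvings)\n",
              x$model, x$mode, x$trace$objective[nrow(x$trace)], x$halvings))
  invisible(x)
}

#' Natural-unit parameter maps from a fit
#'
#' Exponentiates the log-encoded maps back to physical units: `A`
#' (arbitrary units), `R1` and `R2*` (1/s) and `MTsat` (fraction; multiply
#' by 100 for the conventional percent units).
#'
#' @param fit an [mpm_fit()] object (or a [map_stack()]).
#' @return named list of 3-D arrays.
#' @export
parameter_maps <- function(fit) {
  maps <- if (inherits(fit, "mpm_fit")) fit$maps else fit
  if (dim(maps)[4L] != 4L)
    stop("natural-parameter conversion applies to the 4-channel SPGR stack",
         call. = FALSE)
  list(A = array(exp(maps[, , , 1]), dim(maps)[1:3]),
       R1 = array(exp(maps[, , , 2]), dim(maps)[1:3]),
       R2s = array(exp(maps[, , , 3]), dim(maps)[1:3]),
       MTsat = array(sigmoid(maps[, , , 4]), dim(maps)[1:3]))
}
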