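# Base-graphics diagnostics.

#' Plot per-iteration objective traces
#'
#' Log-log plot of the negative log-likelihood per iteration for a sample
#' of voxels from a benchmark run (one panel call per method).
#'
#' @param objective matrix of per-iteration objectives (voxels in rows).
#' @param n_show number of voxel traces to draw.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_objective_traces <- function(objective, n_show = 50, main = "") {
  V <- nrow(objective)
  rows <- seq_len(min(n_show, V))
  it <- seq_len(ncol(objective))
  off <- 1e-12
  graphics::matplot(it, t(objective[rows, , drop = FALSE] + off),
                    type = "l", lty = 1, log = "xy",
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    xlab = "iteration", ylab = "negative log-likelihood",
                    main = main)
  invisible(NULL)
}

#' Plot the step-size diagnostic of a 1-D toy problem
#'
#' Draws `|g|/h` against `|y - y*|` for the proposed and Gauss-Newton
#' preconditioners; the step is monotone wherever the curve stays under
#' the bound line.
#'
#' @param problem a 1-D [toy_problem()].
#' @param span half-width of the grid around the optimum.
#' @param n grid resolution.
#' @return invisibly, the diagnostic data frame for the proposed
#'   preconditioner.
#' @export
plot_step_condition <- function(problem, span = 6, n = 601) {
  ystar <- toy_optimum(problem)
  ys <- seq(ystar - span, ystar + span, length.out = n)
  dp <- check_step_condition(problem, ys, "proposed")
  dg <- check_step_condition(problem, ys, "gn")
  ylim <- c(0, min(max(dg$ratio), 4 * span))
  graphics::plot(ys, dp$bound, type = "l", lty = 2, ylim = ylim,
                 xlab = "y", ylab = "|g|/h", main = problem$kind)
  graphics::lines(ys, dp$ratio, col = "blue")
  graphics::lines(ys, pmin(dg$ratio, ylim[2]), col = "red")
  graphics::legend("top", c("bound |y - y*|", "proposed", "Gauss-Newton"),
                   lty = c(2, 1, 1), col = c("black", "blue", "red"),
                   bty = "n")
  invisible(dp)
}
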