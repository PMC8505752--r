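#' Stack of log-parameter maps on a reconstruction grid
#'
#' A 4-D numeric array `nx x ny x nz x K` holding `K` scalar fields (the
#' four log-encoded parameter maps for the SPGR model, or `C + 1` fields
#' for the ESTATICS model) together with a voxel-to-world affine and the
#' physical voxel size.
#'
#' @param data 4-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param voxel_size length-3 physical spacing, mm.
#' @param names optional channel names.
#' @return object of class `map_stack` (the array with attributes).
#' @export
map_stack <- function(data, affine = NULL, voxel_size = c(1, 1, 1),
                      names = NULL) {
  if (length(dim(data)) != 4L) stop("map stack must be a 4-D array", call. = FALSE)
  if (!all(is.finite(data))) stop("map stack must be finite", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  if (is.null(names)) {
    names <- if (dim(data)[4L] == 4L)
      c("a_tilde", "r1_tilde", "r2_tilde", "delta_tilde")
    else paste0("map", seq_len(dim(data)[4L]))
  }
  structure(data, affine = affine, voxel_size = as.numeric(voxel_size),
            channels = names, class = "map_stack")
}

#' @export
print.map_stack <- function(x, ...) {
  d <- dim(x)
  cat("map_stack:", paste(d[1:3], collapse = " x "), "grid,",
      d[4], "channels (", paste(attr(x, "channels"), collapse = ", "), ")\n")
  cat("voxel size:", paste(attr(x, "voxel_size"), collapse = " x "), "mm\n")
  invisible(x)
}

#' One multi-echo contrast of an MPM session
#'
#' Groups the echo volumes of one contrast (shared flip angle, repetition
#' time and MT state; one echo time per volume) with its estimated noise
#' variance and spatial orientation.
#'
#' @param echoes list of 3-D arrays (one per echo) or a 4-D array with
#'   echoes along the fourth axis.
#' @param flip flip angle, radians.
#' @param tr repetition time, seconds.
#' @param te echo times, seconds, one per echo, sorted ascending.
#' @param mt logical MT-pulse flag.
#' @param sigma2 noise variance (scalar; `NULL` if not yet estimated).
#' @param affine 4x4 voxel-to-world matrix.
#' @param voxel_size physical voxel spacing, mm.
#' @return object of class `contrast_series`.
#' @export
contrast_series <- function(echoes, flip, tr, te, mt = FALSE, sigma2 = NULL,
                            affine = NULL, voxel_size = c(1, 1, 1)) {
  if (is.array(echoes) && length(dim(echoes)) == 4L) {
    echoes <- lapply(seq_len(dim(echoes)[4L]), function(e)
      array(echoes[, , , e], dim(echoes)[1:3]))
  }
  if (!length(echoes)) stop("a series needs at least one echo", call. = FALSE)
  dims <- lapply(echoes, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("all echoes of a series must share one grid", call. = FALSE)
  if (length(te) != length(echoes))
    stop("need one echo time per volume", call. = FALSE)
  if (is.unsorted(te)) {
    o <- order(te)
    te <- te[o]; echoes <- echoes[o]
  }
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(echoes = echoes, flip = flip, tr = tr, te = te,
                 mt = isTRUE(mt), sigma2 = sigma2, affine = affine,
                 voxel_size = as.numeric(voxel_size), dim = dims[[1L]]),
            class = "contrast_series")
}

#' @export
print.contrast_series <- function(x, ...) {
  cat(sprintf("contrast_series: flip %.1f deg, TR %.4g s, %d echoes%s\n",
              x$flip * 180 / pi, x$tr, length(x$echoes),
              if (x$mt) ", MT pulse" else ""))
  invisible(x)
}

#' Regularisation configuration for the joint total variation prior
#'
#' @param lambda nonnegative regularisation factor(s), one per channel
#'   (recycled).
#' @param voxel_size physical spacing in mm; finite differences are divided
#'   by it so `lambda` has a consistent physical meaning across resolutions.
#' @return object of class `jtv_config`.
#' @export
jtv_config <- function(lambda = 10, voxel_size = c(1, 1, 1)) {
  if (any(lambda < 0)) stop("lambda must be nonnegative", call. = FALSE)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(list(lambda = as.numeric(lambda),
                 voxel_size = as.numeric(voxel_size)),
            class = "jtv_config")
}
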