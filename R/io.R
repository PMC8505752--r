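# NIfTI and JSON-sidecar I/O, series grouping, prediction of individual
# echoes, and the z-normalised MSE cross-validation metric.

nifti_write <- function(vol, path, affine) {
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vol <- array(as.numeric(img), dim(img))
  list(data = vol, affine = unclass(aff),
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a list of contrast series as NIfTI volumes with JSON sidecars
#'
#' One file pair per echo volume: `con-<c>_echo-<e>.nii.gz` plus a sidecar
#' with BIDS-compatible keys `FlipAngle` (degrees), `RepetitionTime` (s),
#' `EchoTime` (s) and `MTState` (logical).
#'
#' @param series list of [contrast_series()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame (volume, sidecar per row).
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(series)) {
    sr <- series[[ci]]
    for (e in seq_along(sr$echoes)) {
      stem <- sprintf("con-%d_echo-%d", ci, e)
      vol_path <- file.path(dir, paste0(stem, ".nii.gz"))
      js_path <- file.path(dir, paste0(stem, ".json"))
      nifti_write(sr$echoes[[e]], vol_path, sr$affine)
      meta <- list(FlipAngle = sr$flip * 180 / pi,
                   RepetitionTime = sr$tr, EchoTime = sr$te[e],
                   MTState = sr$mt)
      if (!is.null(sr$sigma2)) meta$NoiseVariance <- sr$sigma2
      jsonlite::write_json(meta, js_path, auto_unbox = TRUE, digits = NA)
      rows[[length(rows) + 1L]] <- data.frame(volume = vol_path,
                                              sidecar = js_path)
    }
  }
  invisible(do.call(rbind, rows))
}

#' Read multi-echo VFA volumes into contrast series
#'
#' Accepts a directory of NIfTI volumes with JSON sidecars, a manifest data
#' frame with columns `volume` and `sidecar`, or a YAML configuration file
#' with a top-level `volumes:` list of `{volume:, sidecar:}` entries.
#' Volumes are grouped into contrasts by (flip angle, TR, MT state) and
#' echoes are sorted by TE; flip angles are converted from degrees to
#' radians (times are taken in seconds, as in BIDS).
#'
#' @param path directory, YAML file, or manifest data frame.
#' @return list of [contrast_series()].
#' @export
read_series <- function(path) {
  if (is.data.frame(path)) {
    manifest <- path
  } else if (dir.exists(path)) {
    vols <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE))
    if (!length(vols)) stop("no NIfTI volumes found in ", path, call. = FALSE)
    side <- sub("\\.nii(\\.gz)?$", ".json", vols)
    manifest <- data.frame(volume = vols, sidecar = side)
  } else if (grepl("\\.(ya?ml)$", path)) {
    cfgy <- yaml::read_yaml(path)
    manifest <- do.call(rbind, lapply(cfgy$volumes, function(v)
      data.frame(volume = v$volume, sidecar = v$sidecar)))
  } else {
    stop("path must be a directory, a YAML config or a manifest data frame",
         call. = FALSE)
  }
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    vp <- manifest$volume[i]; sp <- manifest$sidecar[i]
    if (!file.exists(vp)) stop("missing volume: ", vp, call. = FALSE)
    if (!file.exists(sp)) stop("missing sidecar: ", sp, call. = FALSE)
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    for (key in c("FlipAngle", "RepetitionTime", "EchoTime")) {
      if (is.null(meta[[key]]))
        stop("sidecar ", sp, " lacks required key ", key, call. = FALSE)
    }
    nf <- nifti_read(vp)
    list(vol = nf$data, affine = nf$affine, voxel_size = nf$voxel_size,
         flip = meta$FlipAngle * pi / 180, tr = meta$RepetitionTime,
         te = meta$EchoTime, mt = isTRUE(meta$MTState),
         sigma2 = meta$NoiseVariance)
  })
  key <- vapply(recs, function(r)
    sprintf("%.10g|%.10g|%d", r$flip, r$tr, as.integer(r$mt)), character(1))
  out <- lapply(split(seq_along(recs), key), function(idx) {
    rs <- recs[idx]
    o <- order(vapply(rs, `[[`, numeric(1), "te"))
    rs <- rs[o]
    dims <- dim(rs[[1L]]$vol)
    for (r in rs) if (!identical(dim(r$vol), dims))
      stop("inconsistent grids within one contrast series", call. = FALSE)
    s2 <- rs[[1L]]$sigma2
    contrast_series(lapply(rs, `[[`, "vol"), flip = rs[[1L]]$flip,
                    tr = rs[[1L]]$tr,
                    te = vapply(rs, `[[`, numeric(1), "te"),
                    mt = rs[[1L]]$mt,
                    sigma2 = if (is.null(s2)) NULL else s2,
                    affine = rs[[1L]]$affine,
                    voxel_size = rs[[1L]]$voxel_size)
  })
  names(out) <- NULL
  # stable order: non-MT before MT, descending flip within
  ord <- order(vapply(out, function(s) s$mt, logical(1)),
               -vapply(out, `[[`, numeric(1), "flip"))
  out[ord]
}

#' Write fitted maps as NIfTI volumes plus a JSON run log
#'
#' Emits the natural-unit maps (`R1`, `R2s` in 1/s; `A` in arbitrary
#' units; `MTsat` as a fraction, or percent with `mtsat_percent = TRUE`),
#' the four log-parameter maps, the final IRLS weight field (MAP mode) and
#' a machine-readable `run.json` with the configuration and iteration
#' trace.
#'
#' @param fit an [mpm_fit()] object.
#' @param dir output directory.
#' @param mtsat_percent write MTsat in percent units (x100).
#' @return invisibly, the vector of files written.
#' @export
write_maps <- function(fit, dir, mtsat_percent = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- attr(fit$maps, "affine")
  files <- character(0)
  put <- function(vol, name) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    nifti_write(vol, p, aff)
    files <<- c(files, p)
  }
  if (fit$model == "spgr") {
    pm <- parameter_maps(fit)
    put(pm$A, "A")
    put(pm$R1, "R1")
    put(pm$R2s, "R2s")
    put(pm$MTsat * if (mtsat_percent) 100 else 1, "MTsat")
  }
  ch <- attr(fit$maps, "channels")
  for (k in seq_len(dim(fit$maps)[4L]))
    put(array(fit$maps[, , , k], dim(fit$maps)[1:3]),
        paste0("log_", ch[k]))
  if (!is.null(fit$weights)) put(fit$weights, "jtv_weights")
  log_path <- file.path(dir, "run.json")
  jsonlite::write_json(list(model = fit$model, mode = fit$mode,
                            lambda = fit$cfg$lambda, sigma2 = fit$sigma2,
                            halvings = fit$halvings, trace = fit$trace),
                       log_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, log_path)
  invisible(files)
}

#' Predict one echo volume from fitted maps
#'
#' Pulls the maps to the acquisition grid (if a projection is given) and
#' evaluates the SPGR forward model, yielding the noise-free predicted
#' volume for the acquisition parameters `acq`.
#'
#' @param maps a [map_stack()] (4 channels, SPGR).
#' @param acq an [acq_params()].
#' @param op optional [projection_operator()] to the acquisition grid.
#' @return 3-D array of predicted intensities.
#' @export
predict_echo <- function(maps, acq, op = NULL) {
  Y <- unclass(maps)
  if (!is.null(op)) Y <- pull(Y, op)
  dims <- dim(Y)[1:3]
  k <- spgr_kernel(Y[, , , 1], Y[, , , 2], Y[, , , 3], Y[, , , 4],
                   acq$flip, acq$tr, acq$te, acq$mt)
  array(k$s, dims)
}

#' Z-normalised mean-squared prediction error table
#'
#' Cross-validation metric for held-out echoes: given per-(fold, contrast,
#' echo) mean-squared errors, z-normalises them over the pooled set
#' (a single mean/sd across all rows) and reports the table and its
#' median. Z-scoring removes the arbitrary intensity scale so that methods
#' can be compared across folds, contrasts and echo times.
#'
#' @param mse_table data frame with columns `fold`, `contrast`, `echo`,
#'   `mse`, typically rows from several methods sharing the same folds; an
#'   optional `method` column is preserved.
#' @return list with `table` (input plus a `z` column) and `median_z`
#'   (named per method when a `method` column is present).
#' @export
znorm_mse <- function(mse_table) {
  stopifnot(all(c("fold", "contrast", "echo", "mse") %in% names(mse_table)))
  mu <- mean(mse_table$mse)
  sdv <- stats::sd(mse_table$mse)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  mse_table$z <- (mse_table$mse - mu) / sdv
  med <- if (!is.null(mse_table$method)) {
    tapply(mse_table$z, mse_table$method, stats::median)
  } else {
    stats::median(mse_table$z)
  }
  list(table = mse_table, median_z = med)
}
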