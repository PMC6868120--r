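#' Masked voxel time series
#'
#' The working representation for all temporal operations: a voxels x
#' timepoints matrix together with the 1-based grid coordinates of each voxel
#' and the sampling interval. `censored_frames` records timepoints that were
#' replaced by interpolation during motion scrubbing.
#'
#' @param matrix voxels x timepoints numeric matrix.
#' @param voxel_index voxels x 3 integer matrix of 1-based grid coordinates.
#' @param tr_seconds sampling interval in seconds.
#' @param grid_dim length-3 integer, the 3D grid the coordinates live on.
#' @param censored_frames integer vector of interpolated timepoint indices.
#' @return An object of class `voxel_series`.
#' @export
voxel_series <- function(matrix, voxel_index, tr_seconds, grid_dim = NULL,
                         censored_frames = integer(0)) {
  matrix <- as.matrix(matrix)
  voxel_index <- as.matrix(voxel_index)
  if (nrow(matrix) != nrow(voxel_index))
    stop("voxel_index must have one row per voxel")
  if (ncol(voxel_index) != 3L) stop("voxel_index must have 3 columns")
  if (anyNA(matrix)) stop("voxel series must not contain missing values")
  if (!is.finite(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (is.null(grid_dim)) grid_dim <- apply(voxel_index, 2, max)
  if (any(voxel_index < 1L) || any(t(voxel_index) > grid_dim))
    stop("voxel_index outside grid")
  structure(list(matrix = matrix, voxel_index = voxel_index,
                 tr_seconds = as.numeric(tr_seconds),
                 grid_dim = as.integer(grid_dim),
                 censored_frames = as.integer(censored_frames)),
            class = "voxel_series")
}

#' @export
print.voxel_series <- function(x, ...) {
  cat(sprintf("<voxel_series> %d voxels x %d timepoints, TR %.3g s, %d censored\n",
              nrow(x$matrix), ncol(x$matrix), x$tr_seconds,
              length(x$censored_frames)))
  invisible(x)
}

#' Extract masked time series from a 4D image
#'
#' @param volume 4D [image_volume()].
#' @param mask 3D [image_volume()] on the same grid; nonzero voxels are kept.
#' @return A [voxel_series()].
#' @export
mask_series <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "image_volume"))
  d <- dim(volume$data)
  if (length(d) != 4L) stop("mask_series expects a 4D image")
  if (!all(dim(mask$data) == d[1:3])) stop("mask grid does not match image")
  idx <- which(mask$data != 0)
  if (!length(idx)) stop("empty mask")
  mat <- matrix(volume$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  voxel_series(mat, arrayInd(idx, d[1:3]), volume$tr_seconds,
               grid_dim = d[1:3])
}

#' Re-embed a per-voxel vector or series into grid space
#'
#' @param values length-V vector or V x T matrix aligned with
#'   `series$voxel_index`.
#' @param series the [voxel_series()] supplying geometry.
#' @param fill value outside the mask (default `NaN`).
#' @return A 3D or 4D array on the series grid.
#' @export
series_to_array <- function(values, series, fill = NaN) {
  stopifnot(inherits(series, "voxel_series"))
  gd <- series$grid_dim
  lin <- as.vector((series$voxel_index[, 3] - 1) * gd[1] * gd[2] +
                   (series$voxel_index[, 2] - 1) * gd[1] + series$voxel_index[, 1])
  if (is.matrix(values)) {
    out <- array(fill, c(gd, ncol(values)))
    plane <- prod(gd)
    for (t in seq_len(ncol(values))) out[lin + (t - 1) * plane] <- values[, t]
  } else {
    out <- array(fill, gd)
    out[lin] <- values
  }
  out
}
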