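#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints of a 4D acquisition (signal
#' equilibration / subject adaptation frames). The conventional default is 10.
#'
#' @param volume 4D [image_volume()].
#' @param n_discard number of leading volumes to drop.
#' @return The shortened [image_volume()].
#' @export
discard_initial_volumes <- function(volume, n_discard = 10L) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  if (length(d) != 4L) stop("discard_initial_volumes expects a 4D image")
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be >= 0")
  if (n_discard >= d[4]) stop(sprintf(
    "cannot discard %d of %d volumes", n_discard, d[4]))
  if (n_discard == 0L) return(volume)
  image_volume(volume$data[, , , (n_discard + 1L):d[4], drop = FALSE],
               affine = volume$affine, voxel_size_mm = volume$voxel_size_mm,
               tr_seconds = volume$tr_seconds)
}

#' Framewise displacement
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations converted to arc length on a sphere
#' of `head_radius_mm` (default 50 mm). The first frame has FD 0 by convention.
#'
#' @param motion a `motion_params` object (see [read_motion_params()]).
#' @param head_radius_mm radius used to convert rotations to mm of arc.
#' @param threshold_mm censoring threshold stored alongside the series
#'   (default 0.5 mm).
#' @return An `fd_series` object: list with `fd_mm` and `threshold_mm`.
#' @export
compute_fd <- function(motion, head_radius_mm = 50, threshold_mm = 0.5) {
  stopifnot(inherits(motion, "motion_params"))
  tr <- motion$translations_mm
  ro <- motion$rotations_rad
  if (nrow(tr) < 2L) stop("need at least 2 timepoints to compute FD")
  dtr <- abs(diff(tr))
  dro <- abs(diff(ro)) * head_radius_mm
  fd <- c(0, rowSums(dtr) + rowSums(dro))
  structure(list(fd_mm = fd, threshold_mm = threshold_mm),
            class = "fd_series")
}

#' Scrub high-motion frames by linear interpolation
#'
#' Frames whose FD exceeds the threshold are replaced, per voxel, by linear
#' interpolation between the nearest uncensored neighbours; censored frames at
#' either end take the nearest uncensored value. Uncensored frames are never
#' modified, and interpolated frames stay in the series for the downstream
#' autoregressions (replacement, not deletion).
#'
#' @param series a [voxel_series()].
#' @param fd an `fd_series` from [compute_fd()], same length as the series.
#' @param threshold_mm censoring threshold; defaults to the one stored in `fd`.
#' @return The scrubbed [voxel_series()] with `censored_frames` filled in.
#' @export
scrub_interpolate <- function(series, fd, threshold_mm = NULL) {
  stopifnot(inherits(series, "voxel_series"), inherits(fd, "fd_series"))
  tt <- ncol(series$matrix)
  if (length(fd$fd_mm) != tt)
    stop("FD length does not match timepoint count")
  thr <- threshold_mm %||% fd$threshold_mm
  bad <- which(fd$fd_mm > thr)
  if (!length(bad)) return(series)
  good <- setdiff(seq_len(tt), bad)
  if (!length(good)) stop("all frames exceed the FD threshold")
  # rule = 2: leading/trailing censored frames take the nearest kept value
  interp <- t(apply(series$matrix, 1, function(v)
    approx(good, v[good], xout = seq_len(tt), method = "linear", rule = 2)$y))
  out <- series$matrix
  out[, bad] <- interp[, bad]
  voxel_series(out, series$voxel_index, series$tr_seconds,
               grid_dim = series$grid_dim,
               censored_frames = sort(union(series$censored_frames, bad)))
}

#' Friston-24 motion regressor expansion
#'
#' The 24-column motion model: the six rigid-body parameters, the same six
#' lagged by one frame (first row zero-padded), and the squares of both sets.
#'
#' @param motion a `motion_params` object.
#' @return T x 24 numeric matrix.
#' @export
build_friston24 <- function(motion) {
  stopifnot(inherits(motion, "motion_params"))
  p6 <- cbind(motion$translations_mm, motion$rotations_rad)
  if (nrow(p6) < 2L) stop("need at least 2 timepoints")
  lag <- rbind(0, p6[-nrow(p6), , drop = FALSE])
  out <- cbind(p6, lag, p6^2, lag^2)
  colnames(out) <- c(paste0("rp", 1:6), paste0("rp", 1:6, "_lag"),
                     paste0("rp", 1:6, "_sq"), paste0("rp", 1:6, "_lag_sq"))
  out
}

#' Nuisance regression
#'
#' Replaces every voxel's series by its least-squares residual against an
#' intercept plus the supplied regressors (motion expansion, global mean,
#' tissue signals, ...). Collinear regressor columns are dropped with a
#' warning rather than failing.
#'
#' @param series a [voxel_series()].
#' @param regressors T x k numeric matrix, or `NULL`/zero-column for
#'   intercept-only regression (demeaning).
#' @return The residual [voxel_series()].
#' @export
regress_nuisance <- function(series, regressors = NULL) {
  stopifnot(inherits(series, "voxel_series"))
  tt <- ncol(series$matrix)
  x <- matrix(1, tt, 1)
  if (!is.null(regressors) && NCOL(regressors) > 0) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != tt)
      stop("regressor rows must match timepoint count")
    x <- cbind(x, regressors)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])
    warning(sprintf("dropping %d collinear nuisance column(s)", length(drop)))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  resid <- t(qr.resid(qx, t(series$matrix)))
  voxel_series(resid, series$voxel_index, series$tr_seconds,
               grid_dim = series$grid_dim,
               censored_frames = series$censored_frames)
}

#' Linear detrend
#'
#' Removes each voxel's least-squares line (intercept and slope over time).
#'
#' @param series a [voxel_series()].
#' @return The detrended [voxel_series()].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "voxel_series"))
  tt <- ncol(series$matrix)
  x <- cbind(1, seq_len(tt))
  resid <- t(qr.resid(qr(x), t(series$matrix)))
  voxel_series(resid, series$voxel_index, series$tr_seconds,
               grid_dim = series$grid_dim,
               censored_frames = series$censored_frames)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the filter adds no phase shift — phase matters
#' here because the causality estimates downstream are built on temporal lags.
#' Defaults isolate the 0.01-0.1 Hz band conventionally used for slow
#' hemodynamic fluctuations.
#'
#' @param series a [voxel_series()].
#' @param low_hz,high_hz passband edges; `0 <= low_hz < high_hz < ` Nyquist.
#' @return The filtered [voxel_series()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(series, "voxel_series"))
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyq))
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  tt <- ncol(series$matrix)
  pad <- min(tt - 1L, 30L)
  filt <- t(apply(series$matrix, 1, function(v) {
    # demean and odd-reflect at both ends before the forward-backward pass;
    # zero initial filter states would otherwise leave large edge transients
    mu <- mean(v)
    v <- v - mu
    ext <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[tt] - v[(tt - 1):(tt - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + tt)]
  }))
  voxel_series(filt, series$voxel_index, series$tr_seconds,
               grid_dim = series$grid_dim,
               censored_frames = series$censored_frames)
}

#' Full temporal preprocessing chain
#'
#' Fixed order: discard initial volumes, FD scrubbing with linear
#' interpolation, nuisance regression (Friston-24 motion expansion plus the
#' global mean over the mask unless `global_signal = FALSE`), linear detrend,
#' band-pass. The motion file must cover the retained (post-discard) volumes;
#' if it covers the full acquisition its first `n_discard` rows are dropped to
#' match.
#'
#' @param volume 4D [image_volume()].
#' @param mask 3D [image_volume()].
#' @param motion a `motion_params` object, or `NULL` to skip motion steps.
#' @param n_discard leading volumes to drop (default 10).
#' @param fd_threshold_mm scrubbing threshold (default 0.5).
#' @param band passband in Hz (default `c(0.01, 0.1)`).
#' @param global_signal include the mask-wide mean as a nuisance regressor.
#' @param extra_regressors optional extra T x k nuisance matrix (e.g. tissue
#'   signals), aligned with the retained volumes.
#' @return A [voxel_series()] ready for [compute_gcd_maps()].
#' @export
preprocess_series <- function(volume, mask, motion = NULL, n_discard = 10L,
                              fd_threshold_mm = 0.5, band = c(0.01, 0.1),
                              global_signal = TRUE, extra_regressors = NULL) {
  volume <- discard_initial_volumes(volume, n_discard)
  series <- mask_series(volume, mask)
  tt <- ncol(series$matrix)
  regressors <- NULL
  if (!is.null(motion)) {
    if (nrow(motion$translations_mm) == tt + n_discard)
      motion <- motion_params(
        motion$translations_mm[-seq_len(n_discard), , drop = FALSE],
        motion$rotations_rad[-seq_len(n_discard), , drop = FALSE])
    if (nrow(motion$translations_mm) != tt)
      stop("motion parameter rows do not match retained volumes")
    fd <- compute_fd(motion, threshold_mm = fd_threshold_mm)
    series <- scrub_interpolate(series, fd)
    regressors <- build_friston24(motion)
  }
  if (global_signal)
    regressors <- cbind(regressors, global = colMeans(series$matrix))
  if (!is.null(extra_regressors))
    regressors <- cbind(regressors, as.matrix(extra_regressors))
  series <- regress_nuisance(series, regressors)
  series <- detrend_linear(series)
  bandpass(series, band[1], band[2])
}
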