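#' In-memory image volume
#'
#' Light container for a 3D mask or 4D functional image: the data array, the
#' 4x4 voxel-to-world affine, the voxel size in mm and (for 4D images) the
#' sampling interval in seconds. Grid coordinates are 1-based array indices
#' everywhere in this package; world coordinates are obtained only through the
#' affine.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling by
#'   `voxel_size_mm`.
#' @param voxel_size_mm length-3 positive numeric, edge lengths in mm.
#' @param tr_seconds sampling interval (repetition time) in seconds; required
#'   for 4D data, must be `NULL` for 3D data.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine = NULL, voxel_size_mm = c(1, 1, 1),
                         tr_seconds = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("image data must be a 3D or 4D array")
  if (any(dim(data) <= 0)) stop("image dimensions must be positive")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive numbers")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  if (nd == 4L) {
    if (is.null(tr_seconds) || !is.finite(tr_seconds) || tr_seconds <= 0)
      stop("a 4D image requires tr_seconds > 0; supply the repetition time")
    tr_seconds <- as.numeric(tr_seconds)
  } else if (!is.null(tr_seconds)) {
    stop("tr_seconds only applies to 4D images")
  }
  structure(list(data = data, affine = affine, voxel_size_mm = voxel_size_mm,
                 tr_seconds = tr_seconds),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s, voxel %s mm%s\n",
              paste(d, collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              if (is.null(x$tr_seconds)) ""
              else sprintf(", TR %.3g s", x$tr_seconds)))
  invisible(x)
}

#' Read a NIfTI-1 image
#'
#' Reads a `.nii`/`.nii.gz` file into an [image_volume()]. For 4D files the
#' repetition time is taken from the time-axis pixdim header field; a missing
#' or non-positive header TR is a hard error because the band-pass filter and
#' the autoregressive lag semantics depend on it.
#'
#' @param path path to a NIfTI-1 file.
#' @param tr_seconds optional override for the repetition time (seconds); use
#'   when the header TR is absent or wrong.
#' @return An [image_volume()].
#' @export
read_image <- function(path, tr_seconds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)
  hdr <- RNifti::niftiHeader(img)
  vox <- abs(hdr$pixdim[2:4])
  arr <- array(as.numeric(img), dim = d)
  if (length(d) == 4L) {
    tr <- tr_seconds %||% hdr$pixdim[5]
    if (!is.finite(tr) || tr <= 0)
      stop("4D image ", path, " has no usable TR in its header; ",
           "supply tr_seconds (config key tr_seconds / --tr)")
    image_volume(arr, affine = RNifti::xform(img), voxel_size_mm = vox,
                 tr_seconds = tr)
  } else {
    image_volume(arr, affine = RNifti::xform(img), voxel_size_mm = vox)
  }
}

#' Write a NIfTI-1 image
#'
#' Values are stored as 32-bit float; for 4D volumes the TR is written into the
#' time-axis pixdim field so that [read_image()] round-trips it.
#'
#' @param volume an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  nd <- length(dim(volume$data))
  pd <- c(volume$voxel_size_mm, if (nd == 4L) volume$tr_seconds)
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read rigid-body motion parameters
#'
#' Parses the 6-column whitespace-delimited realignment file convention:
#' three translations (mm) followed by three rotations (radians by default).
#'
#' @param path text file with one row per retained volume and 6 columns.
#' @param degrees if `TRUE` the rotation columns are in degrees and are
#'   converted to radians.
#' @param n_timepoints optional expected row count (e.g. the retained volume
#'   count); a mismatch is an error.
#' @return A `motion_params` object: list with `translations_mm` (T x 3) and
#'   `rotations_rad` (T x 3).
#' @export
read_motion_params <- function(path, degrees = FALSE, n_timepoints = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- tryCatch(as.matrix(read.table(path, header = FALSE)),
                error = function(e) stop("cannot parse motion file ", path,
                                         ": ", conditionMessage(e)))
  if (ncol(m) != 6L) stop("motion file must have 6 columns, got ", ncol(m))
  if (!is.numeric(m) || anyNA(m)) stop("motion file contains non-numeric rows")
  if (!is.null(n_timepoints) && nrow(m) != n_timepoints)
    stop(sprintf("motion file has %d rows but %d timepoints expected",
                 nrow(m), n_timepoints))
  rot <- m[, 4:6, drop = FALSE]
  if (degrees) rot <- rot * pi / 180
  motion_params(m[, 1:3, drop = FALSE], rot)
}

#' @rdname read_motion_params
#' @param translations_mm T x 3 matrix of translations in mm.
#' @param rotations_rad T x 3 matrix of rotations in radians.
#' @export
motion_params <- function(translations_mm, rotations_rad) {
  translations_mm <- as.matrix(translations_mm)
  rotations_rad <- as.matrix(rotations_rad)
  stopifnot(ncol(translations_mm) == 3L, ncol(rotations_rad) == 3L,
            nrow(translations_mm) == nrow(rotations_rad))
  structure(list(translations_mm = translations_mm,
                 rotations_rad = rotations_rad),
            class = "motion_params")
}

#' Read or write a cohort manifest
#'
#' The manifest is a TSV with one subject per row: `subject_id`, `group_label`
#' (`substate_A` / `substate_B`), `image_path`, `motion_path` and the
#' covariates `age`, `sex`, `duration`. Subject ids must be unique and both
#' group labels must be present for any classification run.
#'
#' @param path TSV file path.
#' @return A data.frame with one row per subject.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  man <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("subject_id", "group_label")
  missing <- setdiff(required, names(man))
  if (length(missing)) stop("manifest lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(man$subject_id)) stop("duplicate subject_id in manifest")
  bad <- setdiff(unique(man$group_label), c("substate_A", "substate_B"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  man
}

#' @rdname read_manifest
#' @param manifest data.frame of subjects.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the four density maps of a `gcd_maps` object
#'
#' One 3D NIfTI per metric, named `<prefix>_<metric>.nii.gz`, with `NaN`
#' outside the mask, plus a JSON provenance sidecar (`<prefix>_gcd.json`)
#' recording the significance level and VAR order.
#'
#' @param maps a [gcd_maps] object (see [compute_gcd_maps()]).
#' @param mask a 3D [image_volume()]; nonzero voxels define the analysis mask.
#' @param dir output directory.
#' @param prefix filename prefix, typically the subject id.
#' @return Named character vector of the four map paths, invisibly.
#' @export
write_gcd_maps <- function(maps, mask, dir, prefix) {
  stopifnot(inherits(maps, "gcd_maps"), inherits(mask, "image_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- which(mask$data != 0)
  if (length(idx) != length(maps$inflow))
    stop("mask voxel count does not match map length")
  out <- c(inflow = NA, outflow = NA, totalflow = NA, intflow = NA)
  values <- list(inflow = maps$inflow, outflow = maps$outflow,
                 totalflow = maps$total_flow, intflow = maps$int_flow)
  for (metric in names(values)) {
    vol <- array(NaN, dim(mask$data))
    vol[idx] <- values[[metric]]
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, metric))
    write_image(image_volume(vol, affine = mask$affine,
                             voxel_size_mm = mask$voxel_size_mm), path)
    out[metric] <- path
  }
  jsonlite::write_json(list(prefix = prefix, alpha = maps$alpha,
                            lag_order = maps$lag_order,
                            n_voxels = length(maps$inflow)),
                       file.path(dir, sprintf("%s_gcd.json", prefix)),
                       auto_unbox = TRUE)
  invisible(out)
}

#' @rdname write_gcd_maps
#' @export
read_gcd_maps <- function(mask, dir, prefix) {
  stopifnot(inherits(mask, "image_volume"))
  idx <- which(mask$data != 0)
  get <- function(metric) {
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, metric))
    read_image(path)$data[idx]
  }
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_gcd.json", prefix)))
  gcd_maps(inflow = get("inflow"), outflow = get("outflow"),
           alpha = meta$alpha, lag_order = meta$lag_order)
}
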