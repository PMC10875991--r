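#' 4D CT-perfusion series
#'
#' Container for a dynamic CT acquisition: a 4D Hounsfield-unit array with
#' per-frame acquisition times and voxel geometry. The array layout is
#' `(x, y, z, frame)` with x fastest (column-major), so
#' `matrix(values, ncol = n_frames)` views the data as voxels-by-frames.
#' All frames are assumed to share one grid (inputs are assumed registered).
#'
#' @param values 4D numeric array `(x, y, z, t)`, HU.
#' @param times numeric vector of frame acquisition times (s), strictly
#'   increasing, one per frame; at least 3 frames are required (the tangent
#'   and derivative machinery downstream needs two intervals).
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param origin world coordinate (mm) of the centre of voxel `[1, 1, 1]`.
#' @return an object of class `ctp_series`.
#' @examples
#' arr <- array(0, c(4, 4, 4, 5))
#' s <- ctp_series(arr, times = seq(0, 8, by = 2), spacing = c(1, 1, 1))
#' n_frames(s)
#' @export
ctp_series <- function(values, times, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 4L) stop("`values` must be a 4D (x, y, z, t) array")
  times <- as.numeric(times)
  if (length(times) != dim(values)[4]) {
    stop("length(times) must equal the number of frames (dim 4)")
  }
  if (length(times) < 3L) stop("a CTP series needs at least 3 frames")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive numbers (mm)")
  }
  structure(
    list(values = values, times = times, spacing = spacing,
         origin = as.numeric(origin)),
    class = "ctp_series"
  )
}

#' @rdname ctp_series
#' @param x a `ctp_series`.
#' @export
n_frames <- function(x) dim(x$values)[4]

#' @rdname ctp_series
#' @param i frame index.
#' @export
ctp_frame <- function(x, i) {
  vol3d(x$values[, , , i, drop = TRUE], spacing = x$spacing, origin = x$origin)
}

#' @export
print.ctp_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ctp_series> %d x %d x %d voxels, %d frames\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.3g x %.3g x %.3g mm, times %.3g..%.3g s\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  HU range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# voxels x frames view
series_matrix <- function(series) {
  matrix(series$values, ncol = n_frames(series))
}

#' Read / write volumes and CTP series as NIfTI
#'
#' Thin wrappers over RNifti. A 4D series is stored as a single NIfTI file
#' with the frame interval in `pixdim[5]`; 3D volumes (masks, FG maps, TTP
#' maps) round-trip spacing through `pixdim`. World origin is kept at the
#' `vol3d()` default unless supplied.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param times optional explicit frame times (s); by default frame `i` is at
#'   `(i - 1) * pixdim[5]` (falling back to 1 s spacing if the header has no
#'   time step).
#' @return `read_ctp_series`: a [ctp_series()]; `read_volume`: a [vol3d()]
#'   array; `read_mask`: a logical [vol3d()] array.
#' @export
read_ctp_series <- function(path, times = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::niftiHeader(img)$pixdim
  spacing <- pd[2:4]
  if (is.null(times)) {
    dt <- pd[5]
    if (!is.finite(dt) || dt <= 0) dt <- 1
    times <- (seq_len(dim(arr)[4]) - 1) * dt
  }
  ctp_series(arr, times = times, spacing = spacing)
}

#' @rdname read_ctp_series
#' @param series a [ctp_series()].
#' @export
write_ctp_series <- function(series, path) {
  dt <- if (n_frames(series) > 1L) diff(series$times)[1] else 1
  img <- RNifti::asNifti(series$values)
  RNifti::pixdim(img) <- c(series$spacing, dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ctp_series
#' @param vol a 3D [vol3d()] array (logical masks are written as 0/1).
#' @export
write_volume <- function(vol, path) {
  arr <- vol
  if (is.logical(arr)) arr <- array(as.integer(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol_spacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ctp_series
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  pd <- RNifti::niftiHeader(img)$pixdim
  vol3d(arr, spacing = pd[2:4])
}

#' @rdname read_ctp_series
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  out <- v > 0.5
  attributes(out) <- attributes(v)
  out
}
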