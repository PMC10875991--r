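#' Skull mask by Hounsfield thresholding
#'
#' Marks every voxel of the first frame (the registration benchmark frame,
#' acquired before contrast arrival) with intensity at or above
#' `threshold_hu`. At 155 HU this captures bone while pre-contrast vessels
#' and brain tissue stay well below the threshold.
#'
#' @param series a [ctp_series()].
#' @param threshold_hu scalar threshold (HU), default 155.
#' @return logical [vol3d()] mask with attribute `threshold_hu`.
#' @export
compute_skull_mask <- function(series, threshold_hu = 155) {
  stopifnot(inherits(series, "ctp_series"), is.finite(threshold_hu))
  first <- series$values[, , , 1, drop = TRUE]
  if (any(!is.finite(first))) stop("series contains non-finite voxels")
  m <- vol3d(first >= threshold_hu, spacing = series$spacing,
             origin = series$origin)
  attr(m, "threshold_hu") <- threshold_hu
  m
}

#' Remove skull and extracranial structures from a CTP series
#'
#' Applies the (optionally dilated) skull mask to every frame and discards
#' everything outside the cranial cavity: connected components of the
#' non-skull region that touch the volume border are extracranial, and the
#' brain is taken as the largest enclosed component. If no enclosed component
#' exists (no closed shell in the field of view) the largest non-skull
#' component is kept. Removed voxels are set to the air sentinel
#' (`background`, default -1024 HU) in every frame, so the brain voxel set is
#' identical across frames; in-brain voxels are untouched. The operation is
#' idempotent.
#'
#' @param series a [ctp_series()].
#' @param mask a skull mask from [compute_skull_mask()] (same grid).
#' @param dilate_mm optional dilation margin applied to the mask (mm).
#' @param background sentinel HU for removed voxels.
#' @return a [ctp_series()] with skull and extracranial voxels blanked.
#' @export
strip_skull <- function(series, mask, dilate_mm = 0, background = -1024) {
  stopifnot(inherits(series, "ctp_series"))
  if (!all(dim(mask) == dim(series$values)[1:3])) {
    stop("skull mask grid does not match the series grid")
  }
  if (!any(mask)) return(series)
  m <- mask
  if (dilate_mm > 0) m <- dilate_ball(m, dilate_mm, spacing = series$spacing)
  keep <- array(FALSE, dim(m))
  inv <- !m
  if (any(inv)) {
    cc <- label_components(inv)
    d <- dim(m)
    border_labels <- unique(c(cc$labels[c(1, d[1]), , ],
                              cc$labels[, c(1, d[2]), ],
                              cc$labels[, , c(1, d[3])]))
    border_labels <- setdiff(border_labels, 0L)
    enclosed <- setdiff(seq_along(cc$sizes), border_labels)
    keep_label <- if (length(enclosed) > 0) {
      enclosed[which.max(cc$sizes[enclosed])]
    } else {
      which.max(cc$sizes)
    }
    keep <- cc$labels == keep_label
  }
  vals <- series$values
  drop_lin <- which(!keep)
  nvox <- prod(dim(m))
  for (f in seq_len(n_frames(series))) {
    vals[(f - 1L) * nvox + drop_lin] <- background
  }
  ctp_series(vals, times = series$times, spacing = series$spacing,
             origin = series$origin)
}
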