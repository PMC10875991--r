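#' Rodrigues rotation of vectors about a unit axis
#'
#' `v' = cos(theta) v + (1 - cos(theta)) (u . v) u + sin(theta) (u x v)`.
#' Exact closed form: preserves norms and angles, leaves vectors parallel to
#' the axis unchanged.
#'
#' @param v numeric length-3 vector, or an n x 3 matrix of row vectors.
#' @param axis unit rotation axis (checked to 1e-9).
#' @param angle rotation angle (radians).
#' @return rotated vector(s), same shape as `v`.
#' @examples
#' rotate_vector(c(1, 0, 0), c(0, 0, 1), pi / 2)  # (0, 1, 0)
#' @export
rotate_vector <- function(v, axis, angle) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9) stop("`axis` must be a unit vector")
  was_vec <- is.null(dim(v))
  m <- if (was_vec) matrix(v, 1, 3) else as.matrix(v)
  ct <- cos(angle); st <- sin(angle)
  dot <- as.vector(m %*% axis)
  cx <- cbind(axis[2] * m[, 3] - axis[3] * m[, 2],   # u x v, u = axis
              axis[3] * m[, 1] - axis[1] * m[, 3],
              axis[1] * m[, 2] - axis[2] * m[, 1])
  out <- ct * m + (1 - ct) * outer(dot, axis) + st * cx
  if (was_vec) as.vector(out) else out
}

#' Initial square sampling plane
#'
#' `(2 m + 1) x (2 m + 1)` grid of sample coordinates in the `z = 0` plane,
#' centred on the origin (its own centroid), with uniform spacing. The grid
#' is the template that [propagate_planes()] rotates and translates along
#' the centerline.
#'
#' @param half_size `m`, samples per half-side (>= 1).
#' @param spacing in-plane sample spacing (mm).
#' @return `(2m+1)^2` x 3 matrix with attributes `grid_dim`, `spacing`.
#' @export
initial_plane <- function(half_size, spacing = 0.5) {
  stopifnot(half_size >= 1)
  g <- seq(-half_size, half_size) * spacing
  gr <- as.matrix(expand.grid(x = g, y = g))
  out <- cbind(gr, z = 0)
  attr(out, "grid_dim") <- rep(2L * as.integer(half_size) + 1L, 2L)
  attr(out, "spacing") <- spacing
  out
}

#' Resample a centerline at uniform arc-length steps
#'
#' Linear interpolation of each coordinate against cumulative arc length.
#' Uniform spacing keeps the central-difference tangents (and hence the
#' propagated plane normals) well behaved on unevenly spaced Dijkstra nodes.
#'
#' @param cl a [centerline()].
#' @param step arc-length step (mm).
#' @return a [centerline()] resampled at `seq(0, L, by = step)` (the final
#'   point is always included).
#' @export
resample_centerline <- function(cl, step = 0.5) {
  s <- cl$arc_length
  L <- max(s)
  si <- seq(0, L, by = step)
  if (si[length(si)] < L - 1e-9) si <- c(si, L)
  pts <- vapply(1:3, function(k) approx(s, cl$points[, k], xout = si)$y,
                numeric(length(si)))
  centerline(pts)
}

#' Propagate the sampling plane along a centerline
#'
#' Sequential rotation-minimizing propagation: for each step the angle
#' between adjacent unit tangents, `theta = arccos(n_(i-1) . n_i)`, and the
#' unit rotation axis perpendicular to both are computed; every sample of
#' the previous plane, expressed relative to the previous centerline point,
#' is rotated by ([rotate_vector()]) and translated to the new point. The
#' axis sign is verified per step (rotating `n_(i-1)` must yield `n_i`).
#' Parallel tangents (`theta = 0`, undefined axis) degenerate to a pure
#' translation; anti-parallel tangents are an error (a fold-back of the
#' centerline is nonphysical at millimetre steps). Each plane's normal
#' equals the corresponding tangent, every plane is an isometric copy of the
#' initial grid, and no torsion beyond the minimal sequential rotations is
#' introduced.
#'
#' @param cl a [centerline()]; it is resampled to uniform `step` arc-length
#'   spacing first.
#' @param half_size_mm plane half-side (mm); the full side should cover
#'   about 4 lumen radii.
#' @param in_plane_spacing sample spacing inside each plane (mm).
#' @param step arc-length step between planes (mm).
#' @return object of class `plane_stack`: `planes` (array
#'   `n_samples x 3 x n_planes` of world coordinates), `centers`, `normals`,
#'   `rotations` tibble (`theta`, `ux`, `uy`, `uz`), `grid_dim`,
#'   `in_plane_spacing`, `step`, `arc_length`.
#' @export
propagate_planes <- function(cl, half_size_mm = 6, in_plane_spacing = 0.5,
                             step = 0.5) {
  stopifnot(inherits(cl, "centerline"))
  cl <- resample_centerline(cl, step)
  a <- cl$points
  nrm <- cl$tangents
  n <- nrow(a)
  m <- max(1L, round(half_size_mm / in_plane_spacing))
  P0 <- initial_plane(m, in_plane_spacing)
  gdim <- attr(P0, "grid_dim")
  ns <- nrow(P0)

  rotate_step <- function(from, to) {
    d <- max(-1, min(1, sum(from * to)))
    theta <- acos(d)
    cr <- cross3(from, to)
    crn <- sqrt(sum(cr^2))
    if (theta < 1e-12 || crn < 1e-12) {
      if (d < 0) {
        stop("anti-parallel consecutive tangents; the centerline folds back on itself")
      }
      return(list(theta = 0, axis = c(0, 0, 1)))
    }
    if (theta > pi - 1e-9) {
      stop("anti-parallel consecutive tangents; the centerline folds back on itself")
    }
    axis <- cr / crn
    chk <- rotate_vector(from, axis, theta)
    if (sum((chk - to)^2) > 1e-12) axis <- -axis
    chk <- rotate_vector(from, axis, theta)
    if (sum((chk - to)^2) > 1e-10) stop("rotation-axis construction failed")
    list(theta = theta, axis = axis)
  }

  planes <- array(NA_real_, c(ns, 3L, n))
  thetas <- numeric(n); axes <- matrix(0, n, 3)
  # align the canonical z-normal plane with the first tangent; a tangent
  # anti-parallel to z is handled by rotating about any perpendicular axis
  z0 <- c(0, 0, 1)
  d0 <- max(-1, min(1, sum(z0 * nrm[1, ])))
  cur <- if (d0 < -1 + 1e-12) {
    rotate_vector(P0, c(1, 0, 0), pi)
  } else if (d0 > 1 - 1e-12) {
    P0[, , drop = FALSE]
  } else {
    rs <- rotate_step(z0, nrm[1, ])
    rotate_vector(P0, rs$axis, rs$theta)
  }
  planes[, , 1] <- sweep(unclass(cur)[, 1:3, drop = FALSE], 2L, a[1, ], `+`)
  for (i in 2:n) {
    rs <- rotate_step(nrm[i - 1, ], nrm[i, ])
    rel <- sweep(planes[, , i - 1], 2L, a[i - 1, ], `-`)
    rel <- if (rs$theta == 0) rel else rotate_vector(rel, rs$axis, rs$theta)
    planes[, , i] <- sweep(rel, 2L, a[i, ], `+`)
    thetas[i] <- rs$theta
    axes[i, ] <- rs$axis
  }
  structure(list(planes = planes, centers = a, normals = nrm,
                 rotations = tibble::tibble(theta = thetas, ux = axes[, 1],
                                            uy = axes[, 2], uz = axes[, 3]),
                 grid_dim = gdim, in_plane_spacing = in_plane_spacing,
                 step = step, arc_length = cl$arc_length),
            class = "plane_stack")
}

#' @export
print.plane_stack <- function(x, ...) {
  cat(sprintf("<plane_stack> %d planes of %d x %d samples (%.3g mm in-plane, %.3g mm steps)\n",
              dim(x$planes)[3], x$grid_dim[1], x$grid_dim[2],
              x$in_plane_spacing, x$step))
  invisible(x)
}

#' Resample an image on a propagated plane stack (vessel straightening)
#'
#' Trilinear interpolation of the volume (or of every frame of a 4D series)
#' at each plane's sample coordinates; the planes are stacked along a new
#' z-axis, rendering the curved vessel as a straight tube. Samples falling
#' outside the source grid carry the `sentinel` value.
#'
#' @param x a [ctp_series()], or a 3D [vol3d()] volume (a binary mask is
#'   interpolated as 0/1 occupancy).
#' @param stack a [propagate_planes()] result.
#' @param frames for a series: `"mip"` (temporal maximum-intensity
#'   projection, default), `"all"` (straighten every frame), or a frame
#'   index.
#' @param sentinel value for out-of-grid samples.
#' @return object of class `straightened_volume`: `values` with axes
#'   (in-plane x, in-plane y, along-vessel z\[, frame\]), `spacing`
#'   `(in_plane, in_plane, step)`, `arc_length`.
#' @export
resample_on_planes <- function(x, stack, frames = "mip", sentinel = -1024) {
  stopifnot(inherits(stack, "plane_stack"))
  npl <- dim(stack$planes)[3]
  ns <- dim(stack$planes)[1]
  pts <- matrix(aperm(stack$planes, c(1, 3, 2)), ncol = 3)   # (ns*npl) x 3
  if (inherits(x, "ctp_series")) {
    spacing <- x$spacing; origin <- x$origin
    vols <- if (identical(frames, "mip")) {
      tm <- x$values[, , , 1, drop = TRUE]
      for (f in seq_len(n_frames(x))[-1]) tm <- pmax(tm, x$values[, , , f, drop = TRUE])
      list(tm)
    } else if (identical(frames, "all")) {
      lapply(seq_len(n_frames(x)), function(f) x$values[, , , f, drop = TRUE])
    } else {
      list(x$values[, , , as.integer(frames), drop = TRUE])
    }
  } else {
    spacing <- vol_spacing(x); origin <- vol_origin(x)
    vols <- list(if (is.logical(x)) array(as.numeric(x), dim(x)) else x)
  }
  vox <- world_to_voxel(pts, spacing, origin)
  out <- lapply(vols, function(v) {
    vals <- interp_trilinear(v, vox, fill = sentinel)
    array(vals, c(stack$grid_dim[1], stack$grid_dim[2], npl))
  })
  all_sentinel <- function(o) {
    if (is.na(sentinel)) all(is.na(o)) else isTRUE(all(o == sentinel))
  }
  if (all(vapply(out, all_sentinel, logical(1)))) {
    stop("every plane sample falls outside the source grid")
  }
  values <- if (length(out) == 1L) out[[1]] else {
    arr <- array(0, c(dim(out[[1]]), length(out)))
    for (f in seq_along(out)) arr[, , , f] <- out[[f]]
    arr
  }
  structure(list(values = values,
                 spacing = c(stack$in_plane_spacing, stack$in_plane_spacing,
                             stack$step),
                 arc_length = stack$arc_length, sentinel = sentinel),
            class = "straightened_volume")
}

#' @export
print.straightened_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<straightened_volume> %s (in-plane %.3g mm, steps %.3g mm, length %.4g mm)\n",
              paste(d, collapse = " x "), x$spacing[1], x$spacing[3],
              max(x$arc_length)))
  invisible(x)
}

#' Per-slice lumen caliber profile of a straightened vessel
#'
#' Counts lumen samples (`value >= lumen_threshold`) per straightened slice
#' and converts to mm^2. Slices with area below `low_frac` of the median are
#' flagged stenotic, above `high_frac` dilated; contiguous flagged runs are
#' reported as arc-length intervals, together with the extremal slices.
#' Leading/trailing empty slices (outside the vessel) are ignored.
#'
#' @param sv a [resample_on_planes()] result (binary or high-contrast tube).
#' @param lumen_threshold sample value defining lumen (0.5 for straightened
#'   masks).
#' @param low_frac,high_frac stenosis / dilation flags relative to the
#'   median area.
#' @return object of class `caliber_profile`: `profile` tibble
#'   (`slice`, `s`, `area`, `flag`), `stenosis_intervals`,
#'   `dilation_intervals` (each a list of `c(start_s, end_s)`),
#'   `min_area_s`, `max_area_s`, `median_area`.
#' @export
assess_caliber_profile <- function(sv, lumen_threshold = 0.5, low_frac = 0.75,
                                   high_frac = 1.25) {
  stopifnot(inherits(sv, "straightened_volume"))
  v <- sv$values
  if (length(dim(v)) == 4L) v <- v[, , , 1, drop = TRUE]
  npl <- dim(v)[3]
  px <- sv$spacing[1] * sv$spacing[2]
  area <- vapply(seq_len(npl), function(k) sum(v[, , k] >= lumen_threshold) * px,
                 numeric(1))
  nz <- which(area > 0)
  if (length(nz) == 0L) stop("straightened volume contains no lumen samples")
  keep <- nz[1]:nz[length(nz)]
  s <- sv$arc_length[keep]
  a <- area[keep]
  med <- stats::median(a)
  flag <- ifelse(a < low_frac * med, "stenosis",
                 ifelse(a > high_frac * med, "dilation", "normal"))
  runs_of <- function(kind) {
    r <- rle(flag == kind)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    for (i in seq_along(r$values)) {
      if (r$values[i]) out <- c(out, list(c(s[starts[i]], s[ends[i]])))
    }
    out
  }
  structure(list(
    profile = tibble::tibble(slice = keep, s = s, area = a, flag = flag),
    stenosis_intervals = runs_of("stenosis"),
    dilation_intervals = runs_of("dilation"),
    min_area_s = s[which.min(a)], max_area_s = s[which.max(a)],
    median_area = med),
    class = "caliber_profile")
}

#' @export
print.caliber_profile <- function(x, ...) {
  cat(sprintf("<caliber_profile> %d slices, median area %.3g mm^2\n",
              nrow(x$profile), x$median_area))
  cat(sprintf("  min area at s = %.3g mm, max area at s = %.3g mm\n",
              x$min_area_s, x$max_area_s))
  cat(sprintf("  %d stenotic and %d dilated interval(s) flagged\n",
              length(x$stenosis_intervals), length(x$dilation_intervals)))
  invisible(x)
}
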