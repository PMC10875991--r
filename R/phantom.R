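#' Gamma-variate time-attenuation curve model
#'
#' Standard analytic model of a contrast bolus: zero enhancement before the
#' arrival time `t0`, then
#' `amplitude * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`
#' on top of a flat `baseline`. The curve peaks exactly at
#' `t0 + alpha * beta` with value `baseline + amplitude`, which gives phantoms
#' a closed-form ground-truth time-to-peak.
#'
#' @param t0 bolus arrival time (s).
#' @param alpha,beta gamma-variate shape and scale (dimensionless, s).
#' @param amplitude peak enhancement above baseline (HU).
#' @param baseline flat pre-contrast attenuation (HU).
#' @return object of class `tac_model`.
#' @examples
#' tac <- tac_gamma_variate(t0 = 4, alpha = 3, beta = 2, amplitude = 300)
#' tac_peak_time(tac)  # 10 s
#' @export
tac_gamma_variate <- function(t0 = 4, alpha = 3, beta = 2,
                              amplitude = 300, baseline = 40) {
  stopifnot(alpha > 0, beta > 0, amplitude >= 0)
  structure(list(family = "gamma_variate", t0 = t0, alpha = alpha, beta = beta,
                 amplitude = amplitude, baseline = baseline),
            class = "tac_model")
}

#' @rdname tac_gamma_variate
#' @param tac a `tac_model`.
#' @param t times (s) at which to evaluate the curve.
#' @export
tac_eval <- function(tac, t) {
  tp <- tac$alpha * tac$beta
  dt <- t - tac$t0
  enh <- ifelse(dt <= 0, 0, (dt / tp)^tac$alpha * exp(tac$alpha - dt / tac$beta))
  tac$baseline + tac$amplitude * enh
}

#' @rdname tac_gamma_variate
#' @export
tac_peak_time <- function(tac) tac$t0 + tac$alpha * tac$beta

# ---- parametric curves (arc-length parameterized, world mm) -----------------

param_curve <- function(fun, tangent_fun, length) {
  structure(list(fun = fun, tangent_fun = tangent_fun, length = length),
            class = "param_curve")
}

#' Analytic 3D curves for phantom tube axes
#'
#' Arc-length-parameterized curves used as tube centerlines.
#' `curve_line(start, direction, length)` is a straight segment;
#' `curve_arc(center, radius, u, v, span)` is a circular arc
#' `center + radius * (cos(s / radius) u + sin(s / radius) v)` with
#' orthonormal in-plane directions `u`, `v` and angular span (radians).
#'
#' @param start,direction,length line start point (mm), direction (normalized
#'   internally) and length (mm).
#' @return a `param_curve`; evaluate with `curve_points(curve, ds)` which
#'   returns arc-length samples, points and unit tangents.
#' @export
curve_line <- function(start, direction, length) {
  d <- normalize3(direction)
  param_curve(
    fun = function(s) sweep(outer(s, d), 2, start, `+`),
    tangent_fun = function(s) matrix(d, nrow = base::length(s), ncol = 3, byrow = TRUE),
    length = length
  )
}

#' @rdname curve_line
#' @param center arc centre (mm).
#' @param radius arc radius (mm).
#' @param u,v orthonormal in-plane unit vectors.
#' @param span angular span (radians).
#' @export
curve_arc <- function(center, radius, u, v, span) {
  u <- normalize3(u)
  v <- normalize3(v - sum(v * u) * u)
  param_curve(
    fun = function(s) {
      a <- s / radius
      sweep(radius * (outer(cos(a), u) + outer(sin(a), v)), 2, center, `+`)
    },
    tangent_fun = function(s) {
      a <- s / radius
      -outer(sin(a), u) + outer(cos(a), v)
    },
    length = radius * span
  )
}

#' @rdname curve_line
#' @param curve a `param_curve`.
#' @param ds sample spacing along arc length (mm).
#' @export
curve_points <- function(curve, ds = 0.1) {
  s <- seq(0, curve$length, by = ds)
  if (s[length(s)] < curve$length) s <- c(s, curve$length)
  list(s = s, points = curve$fun(s), tangents = curve$tangent_fun(s))
}

# ---- tube specification -----------------------------------------------------

# piecewise radius profile with cosine tapers at feature boundaries
make_radius_profile <- function(base_radius, features, taper = 2) {
  force(base_radius); force(features); force(taper)
  function(s) {
    r <- rep(base_radius, length(s))
    for (f in features) {
      s0 <- f$interval[1]; s1 <- f$interval[2]
      target <- base_radius * f$factor
      core <- s >= (s0 + taper) & s <= (s1 - taper)
      r[core] <- target
      up <- s >= s0 & s < (s0 + taper)
      r[up] <- base_radius + (target - base_radius) *
        (1 - cos(pi * (s[up] - s0) / taper)) / 2
      dn <- s > (s1 - taper) & s <= s1
      r[dn] <- base_radius + (target - base_radius) *
        (1 - cos(pi * (s1 - s[dn]) / taper)) / 2
    }
    r
  }
}

#' Tube specification for phantom scenes
#'
#' A tube is a parametric axis curve plus a radius profile (piecewise-constant
#' baseline with optional stenosis and dilation segments, cosine-tapered) and
#' optional side branches.
#'
#' @param curve a [curve_line()] / [curve_arc()] axis.
#' @param radius baseline lumen radius (mm), > 0.
#' @param stenosis,dilation optional `c(start_s, end_s, radius_factor)`; a
#'   stenosis factor must be < 1 and a dilation factor > 1; the two intervals
#'   must not overlap.
#' @param branches list of side branches, each
#'   `list(s =, azimuth =, elevation =, length =, radius =)`: attachment arc
#'   length (mm), azimuth about the axis (radians), elevation from the local
#'   tangent (radians; pi/2 is perpendicular), branch length and radius (mm).
#' @param label one of `"artery"`, `"vein"`, `"none"`.
#' @param taper cosine taper length at feature boundaries (mm).
#' @return object of class `tube_spec`.
#' @export
tube_spec <- function(curve, radius = 3, stenosis = NULL, dilation = NULL,
                      branches = list(), label = c("artery", "vein", "none"),
                      taper = 2) {
  label <- match.arg(label)
  stopifnot(inherits(curve, "param_curve"), radius > 0)
  features <- list()
  if (!is.null(stenosis)) {
    if (stenosis[3] >= 1) stop("a stenosis radius_factor must be < 1")
    features <- c(features, list(list(interval = stenosis[1:2], factor = stenosis[3])))
  }
  if (!is.null(dilation)) {
    if (dilation[3] <= 1) stop("a dilation radius_factor must be > 1")
    features <- c(features, list(list(interval = dilation[1:2], factor = dilation[3])))
  }
  if (length(features) == 2L) {
    iv <- rbind(features[[1]]$interval, features[[2]]$interval)
    if (max(iv[, 1]) < min(iv[, 2])) {
      stop("stenosis and dilation intervals overlap")
    }
  }
  for (f in features) {
    if (diff(f$interval) <= 2 * taper) stop("feature interval shorter than its tapers")
    if (f$interval[1] < 0 || f$interval[2] > curve$length) {
      stop("feature interval outside the tube's arc length")
    }
  }
  structure(list(curve = curve, radius = radius, features = features,
                 radius_at = make_radius_profile(radius, features, taper),
                 branches = branches, label = label),
            class = "tube_spec")
}

# ---- rasterization ----------------------------------------------------------

# stamp a polyline of spheres; errors if the tube leaves the grid
stamp_tube <- function(mask, points, radii, spacing, origin, name = "tube") {
  d <- dim(mask)
  h <- ceiling(max(radii) / spacing) + 1L
  offs <- as.matrix(expand.grid(-h[1]:h[1], -h[2]:h[2], -h[3]:h[3]))
  offw <- sweep(offs, 2L, spacing, `*`)
  vox <- world_to_voxel(points, spacing, origin)
  ctr <- round(vox)
  for (i in seq_len(nrow(points))) {
    cand <- sweep(offs, 2L, ctr[i, ], `+`)
    cw <- voxel_to_world(cand, spacing, origin)
    dist <- sqrt(rowSums(sweep(cw, 2L, points[i, ], `-`)^2))
    keep <- dist <= radii[i]
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    if (any(cand < 1L) || any(cand[, 1] > d[1]) || any(cand[, 2] > d[2]) ||
        any(cand[, 3] > d[3])) {
      stop(sprintf("tube '%s' exits the grid; enlarge the phantom volume", name))
    }
    mask[cand] <- TRUE
  }
  mask
}

# sample points/radii of a tube_spec including its branches
tube_samples <- function(spec, ds) {
  cp <- curve_points(spec$curve, ds)
  main <- list(points = cp$points, radii = spec$radius_at(cp$s))
  branch <- list()
  for (b in spec$branches) {
    i <- which.min(abs(cp$s - b$s))
    p <- cp$points[i, ]
    tg <- normalize3(cp$tangents[i, ])
    basis <- plane_basis(tg)
    nvec <- cos(b$azimuth) * basis$e1 + sin(b$azimuth) * basis$e2
    dir <- normalize3(cos(b$elevation) * tg + sin(b$elevation) * nvec)
    r_here <- main$radii[i]
    s_b <- seq(0, b$length, by = ds)
    start <- p + (r_here - b$radius) * nvec
    pts <- sweep(outer(s_b, dir), 2L, start, `+`)
    branch <- c(branch, list(list(points = pts,
                                  radii = rep(b$radius, length(s_b)))))
  }
  list(main = main, branches = branch)
}

rasterize_tube_spec <- function(spec, shape, spacing, origin, ds = NULL,
                                name = "tube") {
  ds <- ds %||% (0.25 * min(spacing))
  sm <- tube_samples(spec, ds)
  main <- array(FALSE, shape)
  main <- stamp_tube(main, sm$main$points, sm$main$radii, spacing, origin, name)
  branch <- array(FALSE, shape)
  for (k in seq_along(sm$branches)) {
    branch <- stamp_tube(branch, sm$branches[[k]]$points, sm$branches[[k]]$radii,
                         spacing, origin, paste0(name, "-branch", k))
  }
  list(main = main, branch = branch)
}

# ---- full CTP scene ---------------------------------------------------------

#' Synthetic 4D CT-perfusion scene
#'
#' Describes a virtual head: tubular "arteries" and "veins" with distinct
#' gamma-variate bolus dynamics (the vein peaking strictly later than the
#' artery), low-amplitude enhancing soft tissue filling an ellipsoidal
#' cranial cavity, an optional high-attenuation skull shell, and additive
#' Gaussian HU noise. [rasterize_scene()] turns the description into a
#' [ctp_series()], an integer label volume and analytic ground-truth
#' centerlines.
#'
#' Default geometry scales with the grid so small test scenes stay valid:
#' the skull is an ellipsoidal shell at 42% of the volume extent, 1000 HU,
#' 1.5 mm thick, and the default artery/vein are arcs inside the cavity.
#'
#' @param tubes list of [tube_spec()]; `NULL` for the default artery + vein
#'   pair.
#' @param artery_tac,vein_tac,soft_tissue_tac [tac_gamma_variate()] models;
#'   the vein peak must be strictly later than the artery peak.
#' @param shape grid size in voxels `(nx, ny, nz)`.
#' @param spacing isotropic voxel spacing (mm).
#' @param times frame times (s); default 20 frames at 2 s.
#' @param skull include the skull shell?
#' @param skull_hu shell attenuation (>= 155 HU so skull masking captures it).
#' @param noise_sigma additive Gaussian noise (HU, applied to every frame).
#' @param seed RNG seed for the noise.
#' @return object of class `phantom_scene`.
#' @export
phantom_scene <- function(tubes = NULL,
                          artery_tac = tac_gamma_variate(4, 3, 2, 300, 40),
                          vein_tac = tac_gamma_variate(8, 4, 3, 250, 40),
                          soft_tissue_tac = tac_gamma_variate(6, 4, 2.5, 30, 40),
                          shape = c(64, 64, 48), spacing = 0.5,
                          times = seq(0, by = 2, length.out = 20),
                          skull = TRUE, skull_hu = 1000,
                          noise_sigma = 0, seed = 1L) {
  if (tac_peak_time(vein_tac) <= tac_peak_time(artery_tac)) {
    stop("the vein TAC must peak strictly later than the artery TAC")
  }
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  extent <- shape * spacing
  center <- extent / 2
  axes_outer <- 0.42 * extent
  if (is.null(tubes)) {
    r_arc <- 0.22 * min(extent[1:2])
    tube_r <- max(2 * max(spacing), 0.05 * min(extent))
    artery <- tube_spec(
      curve_arc(center + c(0, 0, -0.08 * extent[3]), r_arc,
                u = c(1, 0, 0), v = c(0, 1, 0), span = 2.2),
      radius = tube_r, label = "artery")
    vein <- tube_spec(
      curve_arc(center + c(0, 0, 0.08 * extent[3]), r_arc,
                u = c(-1, 0, 0), v = c(0, 1, 0), span = 2.2),
      radius = tube_r * 1.2, label = "vein")
    tubes <- list(artery, vein)
  }
  structure(list(tubes = tubes, artery_tac = artery_tac, vein_tac = vein_tac,
                 soft_tissue_tac = soft_tissue_tac, shape = shape,
                 spacing = spacing, times = times, skull = skull,
                 skull_hu = skull_hu, skull_axes = axes_outer,
                 skull_thickness = 1.5, center = center,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_scene")
}

ellipsoid_mask <- function(shape, spacing, center, axes) {
  xs <- ((seq_len(shape[1]) - 1) * spacing[1] - center[1]) / axes[1]
  ys <- ((seq_len(shape[2]) - 1) * spacing[2] - center[2]) / axes[2]
  zs <- ((seq_len(shape[3]) - 1) * spacing[3] - center[3]) / axes[3]
  q <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  q <= 1
}

#' Rasterize a phantom scene into a CTP series with ground truth
#'
#' Labels are mutually exclusive: 0 background, 1 artery, 2 vein,
#' 3 soft tissue, 4 skull (vessels take priority at overlaps). With
#' `noise_sigma = 0` every voxel's TAC equals its label's analytic model
#' exactly; background stays at 0 HU and the skull shell is constant.
#'
#' @param scene a [phantom_scene()].
#' @return list with `series` ([ctp_series()]), `labels` (integer [vol3d()]),
#'   and `centerlines` (one points-matrix per tube, sub-voxel sampling).
#' @export
rasterize_scene <- function(scene) {
  shape <- scene$shape
  spacing <- scene$spacing
  origin <- c(0, 0, 0)
  labels <- array(0L, shape)
  centerlines <- list()
  artery <- array(FALSE, shape)
  vein <- array(FALSE, shape)
  for (i in seq_along(scene$tubes)) {
    spec <- scene$tubes[[i]]
    ras <- rasterize_tube_spec(spec, shape, spacing, origin,
                               name = paste0(spec$label, i))
    m <- ras$main | ras$branch
    if (spec$label == "artery") artery <- artery | m
    if (spec$label == "vein") vein <- vein | m
    centerlines[[i]] <- curve_points(spec$curve, 0.25 * min(spacing))$points
  }
  vein <- vein & !artery
  skull <- array(FALSE, shape)
  cavity <- array(TRUE, shape)
  if (scene$skull) {
    outer_m <- ellipsoid_mask(shape, spacing, scene$center, scene$skull_axes)
    inner_m <- ellipsoid_mask(shape, spacing, scene$center,
                              scene$skull_axes - scene$skull_thickness)
    skull <- outer_m & !inner_m
    cavity <- inner_m
  }
  if (any((artery | vein) & !cavity)) {
    stop("a tube extends outside the cranial cavity; shrink the tubes or drop the skull")
  }
  soft <- cavity & !artery & !vein
  labels[soft] <- 3L
  labels[skull] <- 4L
  labels[vein] <- 2L
  labels[artery] <- 1L

  tt <- scene$times
  nt <- length(tt)
  values <- array(0, c(shape, nt))
  lin <- list(`1` = which(labels == 1L), `2` = which(labels == 2L),
              `3` = which(labels == 3L), `4` = which(labels == 4L))
  tacs <- list(`1` = scene$artery_tac, `2` = scene$vein_tac,
               `3` = scene$soft_tissue_tac)
  nvox <- prod(shape)
  for (f in seq_len(nt)) {
    fr <- array(0, shape)
    for (k in c("1", "2", "3")) fr[lin[[k]]] <- tac_eval(tacs[[k]], tt[f])
    fr[lin[["4"]]] <- scene$skull_hu
    values[(f - 1L) * nvox + seq_len(nvox)] <- fr
  }
  if (scene$noise_sigma > 0) {
    set.seed(scene$seed)
    values <- values + rnorm(length(values), sd = scene$noise_sigma)
  }
  list(series = ctp_series(values, times = tt, spacing = spacing),
       labels = vol3d(labels, spacing = spacing),
       centerlines = centerlines)
}

# ---- geometric validation phantoms ------------------------------------------

#' Curved-tube phantom with side branches for centerline validation
#'
#' A curved main tube (circular arc, randomized radius of curvature and span)
#' with `n_branches` side branches attached at randomized, well-separated arc
#' positions. The analytic arc axis is returned as the reference centerline;
#' the seeds are its endpoints. Branches perturb wall-based cross-section
#' centroids, which is exactly what the validation exercises.
#'
#' @param n_branches number of side branches (0, 3 and 6 are the validated
#'   configurations; any count >= 0 works).
#' @param seed RNG seed (branch placement and arc geometry).
#' @param spacing isotropic voxel spacing (mm).
#' @param main_radius tube lumen radius (mm).
#' @param branch_length,branch_elevation branch length (mm) and angle from
#'   the local tangent (radians).
#' @param branch_radius_range branch radius as a fraction of `main_radius`,
#'   sampled uniformly in this range.
#' @return list: `mask` (logical [vol3d()], main tube + branches),
#'   `main_mask`, `branch_mask`, `reference` (dense analytic axis points,
#'   n x 3 mm), `seeds` (`start`, `end`), `n_branches`.
#' @export
make_deviation_phantom <- function(n_branches = 0, seed = 1L, spacing = 0.5,
                                   main_radius = 3, branch_length = 8,
                                   branch_elevation = pi / 3,
                                   branch_radius_range = c(0.4, 0.6)) {
  stopifnot(n_branches >= 0)
  set.seed(seed)
  arc_radius <- runif(1, 35, 45)
  span <- runif(1, 60, 80) * pi / 180
  L <- arc_radius * span
  branches <- list()
  if (n_branches > 0) {
    lo <- 0.15 * L; hi <- 0.85 * L
    # stratified placement: one branch per equal arc slot, jittered within
    # it, so attachment points keep a guaranteed separation
    slot <- (hi - lo) / n_branches
    s_pos <- lo + (seq_len(n_branches) - runif(n_branches, 0.3, 0.7)) * slot
    # successive azimuths a golden angle apart so neighbouring branches
    # leave in well-separated directions and never merge
    az <- runif(1, 0, 2 * pi) + (seq_len(n_branches) - 1) * 2.399963 +
      runif(n_branches, -0.3, 0.3)
    rf <- runif(n_branches, branch_radius_range[1], branch_radius_range[2])
    branches <- lapply(seq_len(n_branches), function(i) {
      list(s = s_pos[i], azimuth = az[i], elevation = branch_elevation,
           length = branch_length, radius = rf[i] * main_radius)
    })
  }
  curve0 <- curve_arc(c(0, 0, 0), arc_radius, u = c(1, 0, 0), v = c(0, 1, 0),
                      span = span)
  margin <- main_radius + branch_length + main_radius + 2
  pts <- curve_points(curve0, 0.5)$points
  lo_w <- apply(pts, 2, min) - margin
  hi_w <- apply(pts, 2, max) + margin
  shape <- ceiling((hi_w - lo_w) / spacing) + 1L
  origin <- lo_w
  shift <- -lo_w
  curve <- curve_arc(shift, arc_radius, u = c(1, 0, 0), v = c(0, 1, 0),
                     span = span)
  spec <- tube_spec(curve, radius = main_radius, branches = branches,
                    label = "none")
  ras <- rasterize_tube_spec(spec, shape, rep(spacing, 3), c(0, 0, 0),
                             name = "deviation-main")
  ref <- curve_points(curve, 0.05)
  mask <- ras$main | ras$branch
  list(mask = vol3d(mask, spacing = rep(spacing, 3)),
       main_mask = vol3d(ras$main, spacing = rep(spacing, 3)),
       branch_mask = vol3d(ras$branch, spacing = rep(spacing, 3)),
       reference = ref$points,
       reference_s = ref$s,
       seeds = list(start = ref$points[1, ], end = ref$points[nrow(ref$points), ]),
       n_branches = n_branches, arc_radius = arc_radius, span = span,
       length = L, spacing = rep(spacing, 3))
}

#' Tube phantom with one stenosis and one dilation
#'
#' A gently curved tube (150 mm radius of curvature) of baseline radius
#' `radius` carrying one narrowed and one dilated segment at randomized,
#' non-overlapping arc-length intervals. The intervals are returned as ground
#' truth for caliber-localization validation.
#'
#' @param seed RNG seed (feature placement and order).
#' @param spacing isotropic voxel spacing (mm).
#' @param tube_length tube arc length (mm).
#' @param radius baseline lumen radius (mm).
#' @param stenosis_factor,dilation_factor radius factors (< 1, > 1).
#' @param feature_length length of each feature segment (mm).
#' @param taper cosine taper at segment boundaries (mm).
#' @return list: `mask` (logical [vol3d()]), `stenosis` and `dilation`
#'   (ground-truth `c(start_s, end_s)` mm), `reference` (analytic axis),
#'   `seeds`, and the radius profile function `radius_at(s)`.
#' @export
make_stenosis_phantom <- function(seed = 1L, spacing = 0.5, tube_length = 60,
                                  radius = 3, stenosis_factor = 0.5,
                                  dilation_factor = 1.5, feature_length = 10,
                                  taper = 2) {
  set.seed(seed)
  L <- tube_length
  first_lo <- runif(1, 6, L / 2 - feature_length - 3)
  second_lo <- runif(1, L / 2 + 3, L - feature_length - 6)
  iv1 <- c(first_lo, first_lo + feature_length)
  iv2 <- c(second_lo, second_lo + feature_length)
  if (runif(1) < 0.5) {
    stenosis <- iv1; dilation <- iv2
  } else {
    stenosis <- iv2; dilation <- iv1
  }
  arc_radius <- 150
  span <- L / arc_radius
  margin <- radius * dilation_factor + 3
  curve0 <- curve_arc(c(0, 0, 0), arc_radius, u = c(1, 0, 0), v = c(0, 1, 0),
                      span = span)
  pts <- curve_points(curve0, 0.5)$points
  lo_w <- apply(pts, 2, min) - margin
  hi_w <- apply(pts, 2, max) + margin
  shape <- ceiling((hi_w - lo_w) / spacing) + 1L
  curve <- curve_arc(-lo_w, arc_radius, u = c(1, 0, 0), v = c(0, 1, 0),
                     span = span)
  spec <- tube_spec(curve, radius = radius,
                    stenosis = c(stenosis, stenosis_factor),
                    dilation = c(dilation, dilation_factor),
                    taper = taper)
  ras <- rasterize_tube_spec(spec, shape, rep(spacing, 3), c(0, 0, 0),
                             name = "stenosis-tube")
  ref <- curve_points(curve, 0.05)
  list(mask = vol3d(ras$main, spacing = rep(spacing, 3)),
       stenosis = stenosis, dilation = dilation,
       reference = ref$points, reference_s = ref$s,
       seeds = list(start = ref$points[1, ], end = ref$points[nrow(ref$points), ]),
       radius_at = spec$radius_at, length = L, spacing = rep(spacing, 3))
}

#' Write a phantom to disk (NIfTI + JSON ground truth)
#'
#' Writes the rasterized series/labels (or mask) as NIfTI next to a JSON
#' sidecar holding the analytic ground truth: centerline points, feature
#' intervals, TAC parameters and the seed.
#'
#' @param x result of [rasterize_scene()], [make_deviation_phantom()] or
#'   [make_stenosis_phantom()].
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(x, dir, name = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  gt <- list()
  if (!is.null(x$series)) {
    p <- file.path(dir, paste0(name, "_series.nii.gz"))
    write_ctp_series(x$series, p)
    paths <- c(paths, p)
    p <- file.path(dir, paste0(name, "_labels.nii.gz"))
    write_volume(x$labels, p)
    paths <- c(paths, p)
    gt$centerlines <- lapply(x$centerlines, function(m) unname(apply(m, 1, c, simplify = FALSE)))
    gt$times <- x$series$times
  } else {
    p <- file.path(dir, paste0(name, "_mask.nii.gz"))
    write_volume(x$mask, p)
    paths <- c(paths, p)
    gt$reference <- unname(apply(x$reference, 1, c, simplify = FALSE))
    gt$seeds <- x$seeds
    gt$stenosis <- x$stenosis
    gt$dilation <- x$dilation
    gt$n_branches <- x$n_branches
  }
  pj <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(gt, pj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, pj))
}
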