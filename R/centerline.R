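#' Vessel wall (outer contour) image
#'
#' One-voxel-thick shell of a binary vessel-of-interest mask: the mask minus
#' its 6-neighbourhood erosion. A single-voxel mask is its own wall (erosion
#' empties it). If the mask has several connected components the largest is
#' used, with a warning.
#'
#' @param mask logical 3D [vol3d()] mask.
#' @return logical [vol3d()] wall mask.
#' @export
extract_wall <- function(mask) {
  if (!any(mask)) stop("vessel-of-interest mask is empty")
  m <- largest_component(mask, warn_multiple = TRUE, what = "vessel-of-interest mask")
  wall <- m & !erode6(m)
  attributes(wall) <- attributes(mask)
  wall
}

# ---- marching tetrahedra ----------------------------------------------------

# Kuhn 6-tetrahedra decomposition of the unit cube; corner codes x=1,y=2,z=4
.tet_corners <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L)
)
.corner_offsets <- cbind(
  x = bitwAnd(0:7, 1L), y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
  z = bitwAnd(bitwShiftR(0:7, 2L), 1L)
)

# isosurface triangles of scalar field F (grid-index coordinates, 1-based)
marching_tetrahedra <- function(F_, iso = 0.5) {
  d <- dim(F_)
  inside <- F_ >= iso
  i1 <- 1:(d[1] - 1L); i2 <- 2:d[1]
  j1 <- 1:(d[2] - 1L); j2 <- 2:d[2]
  k1 <- 1:(d[3] - 1L); k2 <- 2:d[3]
  csum <- inside[i1, j1, k1] + inside[i2, j1, k1] + inside[i1, j2, k1] +
    inside[i2, j2, k1] + inside[i1, j1, k2] + inside[i2, j1, k2] +
    inside[i1, j2, k2] + inside[i2, j2, k2]
  cells <- which(csum > 0L & csum < 8L, arr.ind = TRUE)
  if (nrow(cells) == 0L) {
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  }
  n1 <- d[1]; n12 <- d[1] * d[2]
  base_lin <- cells[, 1] + (cells[, 2] - 1L) * n1 + (cells[, 3] - 1L) * n12
  corner_lin <- sapply(1:8, function(b) {
    o <- .corner_offsets[b, ]
    base_lin + o[1] + o[2] * n1 + o[3] * n12
  })                                        # ncells x 8

  e1_all <- integer(0); e2_all <- integer(0); tri_row <- integer(0)
  n_tri <- 0L
  emit <- function(edges_mat) {
    # edges_mat: (3k) x 2 matrix of global endpoint ids, rows grouped in triples
    e1_all <<- c(e1_all, edges_mat[, 1])
    e2_all <<- c(e2_all, edges_mat[, 2])
  }
  others <- function(a) setdiff(1:4, a)
  for (t in 1:6) {
    A <- corner_lin[, .tet_corners[t, ] + 1L, drop = FALSE]   # ncells x 4
    Vv <- matrix(F_[A], ncol = 4L)
    I <- Vv >= iso
    cnt <- rowSums(I)
    for (a in 1:4) {   # exactly one corner inside (or outside)
      for (mode in c("in", "out")) {
        rows <- if (mode == "in") which(cnt == 1L & I[, a]) else which(cnt == 3L & !I[, a])
        if (length(rows) == 0L) next
        bcd <- others(a)
        tri <- cbind(
          rbind(cbind(A[rows, a], A[rows, bcd[1]]),
                cbind(A[rows, a], A[rows, bcd[2]]),
                cbind(A[rows, a], A[rows, bcd[3]]))
        )
        # interleave so rows come in triangle triples
        m <- length(rows)
        ord <- as.vector(t(matrix(seq_len(3L * m), nrow = m)))
        emit(tri[ord, , drop = FALSE])
      }
    }
    pairs <- utils::combn(4L, 2L)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      rows <- which(cnt == 2L & I[, a] & I[, b])
      if (length(rows) == 0L) next
      cd <- setdiff(1:4, c(a, b))
      # quad on edges (a,c) (a,d) (b,d) (b,c) -> triangles 1-2-3, 1-3-4
      q1 <- cbind(A[rows, a], A[rows, cd[1]])
      q2 <- cbind(A[rows, a], A[rows, cd[2]])
      q3 <- cbind(A[rows, b], A[rows, cd[2]])
      q4 <- cbind(A[rows, b], A[rows, cd[1]])
      m <- length(rows)
      tri <- rbind(q1, q2, q3,  q1, q3, q4)
      ord <- as.vector(t(matrix(seq_len(3L * m), nrow = m)))
      emit(rbind(tri[ord, , drop = FALSE],
                 tri[3L * m + ord, , drop = FALSE]))
    }
  }
  if (length(e1_all) == 0L) {
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  }
  lo <- pmin(e1_all, e2_all)
  hi <- pmax(e1_all, e2_all)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  lo_u <- lo[uk]; hi_u <- hi[uk]
  f_lo <- F_[lo_u]; f_hi <- F_[hi_u]
  tt <- (iso - f_lo) / (f_hi - f_lo)
  p_lo <- arrayInd(lo_u, d)
  p_hi <- arrayInd(hi_u, d)
  verts <- p_lo + tt * (p_hi - p_lo)
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  faces <- faces[!degen, , drop = FALSE]
  list(vertices = verts, faces = faces)
}

#' Triangle surface mesh of a binary volume
#'
#' Extracts the 0.5-isosurface of the (lightly Gaussian-smoothed) binary
#' volume with a marching-tetrahedra pass over the Kuhn 6-tetrahedra cube
#' decomposition, which yields a closed, crack-free triangle surface. The
#' smoothing (default 1 voxel sigma) turns the staircase voxel boundary into
#' a sub-voxel-accurate surface; for a rasterized ball the mesh area matches
#' the analytic sphere area to a few percent. Vertices are in world mm.
#'
#' @param mask logical (or numeric in `[0, 1]`) 3D [vol3d()] volume.
#' @param smooth_sigma pre-smoothing sigma in voxels; 0 disables.
#' @return object of class `triangle_mesh`: `vertices` (n x 3 mm), `faces`
#'   (m x 3 vertex indices).
#' @export
build_mesh <- function(mask, smooth_sigma = 1) {
  spacing <- vol_spacing(mask)
  origin <- vol_origin(mask)
  m <- mask > 0.5
  if (!any(m)) stop("mask is empty; cannot build a mesh")
  idx <- which(m, arr.ind = TRUE)
  pad <- ceiling(3 * max(smooth_sigma, 1)) + 2L
  d <- dim(m)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] * 1
  # zero border guarantees a closed isosurface even when the mask touches
  # the volume boundary
  bd <- 2L
  emb <- array(0, dim(sub) + 2L * bd)
  emb[bd + seq_len(dim(sub)[1]), bd + seq_len(dim(sub)[2]),
      bd + seq_len(dim(sub)[3])] <- sub
  lo <- lo - bd
  F_ <- smooth3(emb, smooth_sigma)
  mt <- marching_tetrahedra(F_, iso = 0.5)
  if (nrow(mt$faces) == 0L) {
    stop("mask is degenerate (no closed isosurface); need a volumetric mask")
  }
  verts_idx <- sweep(mt$vertices, 2L, lo - 1L, `+`)   # back to full-grid index
  verts <- voxel_to_world(verts_idx, spacing, origin)
  structure(list(vertices = verts, faces = mt$faces,
                 spacing = spacing), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Mesh summaries
#'
#' `mesh_area` sums triangle areas (mm^2); `mesh_euler` returns the Euler
#' characteristic `V - E + F` (2 for a closed genus-0 surface).
#'
#' @param mesh a [build_mesh()] result.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh_area
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nE <- length(unique(key))
  nV <- length(unique(as.vector(f)))
  nV - nE + nrow(f)
}

# ---- plane / mesh intersection ----------------------------------------------

# intersect mesh with plane (point, unit normal); returns list of ordered
# contours (k x 3 matrices). Open chains (should not occur on closed meshes)
# are returned as-is.
slice_mesh <- function(mesh, point, normal) {
  dv <- as.vector(sweep(mesh$vertices, 2L, point, `-`) %*% normal)
  dv[dv == 0] <- 1e-12
  f <- mesh$faces
  s1 <- dv[f[, 1]]; s2 <- dv[f[, 2]]; s3 <- dv[f[, 3]]
  crossing <- !((s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0))
  if (!any(crossing)) return(list())
  fc <- f[crossing, , drop = FALSE]
  sc <- cbind(s1[crossing], s2[crossing], s3[crossing])
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  seg_keys <- matrix(NA_character_, nrow(fc), 2L)
  pts_env <- new.env(parent = emptyenv())
  for (ep in edge_pairs) {
    i <- ep[1]; j <- ep[2]
    hit <- sc[, i] * sc[, j] < 0
    if (!any(hit)) next
    vi <- fc[hit, i]; vj <- fc[hit, j]
    tt <- sc[hit, i] / (sc[hit, i] - sc[hit, j])
    p <- mesh$vertices[vi, , drop = FALSE] +
      tt * (mesh$vertices[vj, , drop = FALSE] - mesh$vertices[vi, , drop = FALSE])
    key <- paste(pmin(vi, vj), pmax(vi, vj))
    for (r in seq_along(key)) assign(key[r], p[r, ], envir = pts_env)
    rows <- which(hit)
    first <- is.na(seg_keys[rows, 1])
    seg_keys[rows[first], 1] <- key[first]
    seg_keys[rows[!first], 2] <- key[!first]
  }
  ok <- !is.na(seg_keys[, 1]) & !is.na(seg_keys[, 2])
  seg_keys <- seg_keys[ok, , drop = FALSE]
  if (nrow(seg_keys) == 0L) return(list())
  # adjacency: each edge key borders (on a closed manifold) exactly 2 segments
  all_keys <- unique(as.vector(seg_keys))
  k1 <- match(seg_keys[, 1], all_keys)
  k2 <- match(seg_keys[, 2], all_keys)
  inc <- vector("list", length(all_keys))
  for (s in seq_len(nrow(seg_keys))) {
    inc[[k1[s]]] <- c(inc[[k1[s]]], s)
    inc[[k2[s]]] <- c(inc[[k2[s]]], s)
  }
  used <- logical(nrow(seg_keys))
  contours <- list()
  for (s0 in seq_len(nrow(seg_keys))) {
    if (used[s0]) next
    used[s0] <- TRUE
    chain <- k1[s0]
    cur_key <- k2[s0]
    repeat {
      chain <- c(chain, cur_key)
      nxt <- inc[[cur_key]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      s <- nxt[1]
      used[s] <- TRUE
      cur_key <- if (k1[s] == cur_key) k2[s] else k1[s]
      if (cur_key == chain[1]) break
    }
    pts <- t(vapply(all_keys[chain], function(k) get(k, envir = pts_env),
                    numeric(3)))
    if (nrow(pts) >= 3L) contours <- c(contours, list(unname(pts)))
  }
  contours
}

# area-weighted (shoelace) centroid of a closed 3D contour lying in a plane;
# r_prior (mm) is the running clean-lumen radius used to re-fit the centre of
# junction-merged contours with the radius held fixed
contour_centroid <- function(pts, normal, r_prior = NULL) {
  basis <- plane_basis(normal)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2L, ctr, `-`)
  x <- rel %*% basis$e1
  y <- rel %*% basis$e2
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  per <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  if (abs(A) < 1e-9) {
    return(list(centroid = ctr, area = 0, perimeter = per, circularity = 0))
  }
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  centroid2d <- c(cx, cy)
  circ <- 4 * pi * abs(A) / per^2
  # Lumen centre: the raw polygon centroid of a junction-merged contour is
  # dragged toward the branch opening; a trimmed algebraic (Kasa) circle fit
  # keeps the centre of the dominant circular lumen instead, much closer to
  # the largest-inscribed-sphere definition of a centerline point. On clean
  # (near-circular) sections it coincides with the polygon centroid.
  fit <- robust_circle_center(cbind(x, y), centroid2d)
  if (circ < 0.985) {
    # lumen-radius continuity: on a non-circular (merged) contour, re-fit
    # the centre with the radius held fixed; the lumen arc dominates the
    # votes, the branch opening does not. The running clean-slice radius is
    # used only when consistent with the contour's own robust radius, so a
    # genuine caliber change (stenosis/dilation taper) never inherits a
    # stale prior that would bias the fit sideways.
    r_est <- stats::median(sqrt((x - fit[1])^2 + (y - fit[2])^2))
    r0 <- if (!is.null(r_prior) && is.finite(r_prior) &&
              r_est > 0.75 * r_prior && r_est < 1.35 * r_prior) r_prior else r_est
    fr <- fixed_radius_center(cbind(x, y), r0, fit)
    if (fr$support >= 0.4) fit <- fr$center
  }
  list(centroid = ctr + fit[1] * basis$e1 + fit[2] * basis$e2, area = abs(A),
       perimeter = per, circularity = circ)
}

# centre of a circle of KNOWN radius r0 through the dominant subset of pts:
# Tukey-weighted iteration on the centres implied by each point
fixed_radius_center <- function(pts, r0, init) {
  ctr <- init
  n <- nrow(pts)
  for (it in 1:20) {
    dx <- ctr[1] - pts[, 1]; dy <- ctr[2] - pts[, 2]
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    res <- d - r0
    sc <- 0.25 * r0
    w <- (1 - pmin(1, (res / sc)^2))^2
    if (sum(w) < 1e-9) return(list(center = init, support = 0))
    impx <- pts[, 1] + (r0 / d) * dx
    impy <- pts[, 2] + (r0 / d) * dy
    new_ctr <- c(sum(w * impx), sum(w * impy)) / sum(w)
    shift <- sqrt(sum((new_ctr - ctr)^2))
    ctr <- new_ctr
    if (shift < 1e-7) break
  }
  d <- sqrt((ctr[1] - pts[, 1])^2 + (ctr[2] - pts[, 2])^2)
  support <- mean(abs(d - r0) < 0.15 * r0)
  list(center = ctr, support = support)
}

# robust circle fit in 2D: trimmed algebraic (Kasa) fit followed by a
# redescending IRLS refinement, so the centre tracks the dominant circular
# lumen even when a branch opening contributes a large share of the contour
robust_circle_center <- function(pts, init) {
  n <- nrow(pts)
  if (n < 8L) return(init)
  keep <- rep(TRUE, n)
  ctr <- init
  kasa <- function(P, w = NULL) {
    M <- cbind(2 * P[, 1], 2 * P[, 2], 1)
    rhs <- P[, 1]^2 + P[, 2]^2
    if (!is.null(w)) {
      M <- M * w
      rhs <- rhs * w
    }
    sol <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) NULL else sol[1:2]
  }
  for (it in 1:5) {
    P <- pts[keep, , drop = FALSE]
    if (nrow(P) < 6L) return(init)
    sol <- kasa(P)
    if (is.null(sol)) return(init)
    ctr <- sol
    r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    med <- stats::median(r[keep])
    dev <- abs(r - med)
    mad <- stats::median(dev[keep])
    if (!is.finite(mad) || mad < 1e-6) break
    new_keep <- dev <= 3 * mad + 0.05 * med
    if (sum(new_keep) < 6L || all(new_keep == keep)) break
    keep <- new_keep
  }
  # Tukey-weighted refinement: only points close to the current circle keep
  # influence, which lets the fit escape a compromise between lumen and bump
  for (it in 1:15) {
    r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    med <- stats::median(r)
    sc <- 0.45 * med
    w <- (1 - pmin(1, ((r - med) / sc)^2))^2
    if (sum(w > 0) < 6L) break
    sol <- kasa(pts, sqrt(w))
    if (is.null(sol)) break
    shift <- sqrt(sum((sol - ctr)^2))
    ctr <- sol
    if (shift < 1e-6) break
  }
  # sanity clamp: a degenerate fit (near-collinear retained arc) can throw
  # the centre far out; fall back to the polygon centroid then
  r_est <- stats::median(sqrt((pts[, 1] - init[1])^2 + (pts[, 2] - init[2])^2))
  if (sqrt(sum((ctr - init)^2)) > 0.6 * r_est) return(init)
  ctr
}

#' Cross-section centroid graph of a vessel mesh
#'
#' Marches a slicing plane from the start seed toward the end seed: the
#' plane normal is initialized from the seed pair and re-estimated from the
#' last two accepted centroids, keeping sections near-orthogonal in curved
#' vessels. Every closed mesh/plane intersection contour contributes one
#' area-weighted centroid node (side branches yield separate nodes);
#' centroids of adjacent slices are connected by Euclidean-distance-weighted
#' edges. Seeds snap to the nearest centroid within 5 mm.
#'
#' @param mesh a [build_mesh()] result.
#' @param start,end seed points (world mm) near the vessel lumen ends.
#' @param step slice spacing along the vessel (mm).
#' @param max_steps marching limit; default scales with the seed distance.
#' @param max_skip connect each slice's centroids to centroids up to this
#'   many slices ahead. The shortest path runs among all centroids, and the
#'   extra edges let it hop over sections whose single merged contour is
#'   distorted by a joining side branch (a laterally displaced centroid
#'   lengthens any route through it, so the path bypasses it whenever a
#'   skip edge is available); on curved vessels the corner cut by a skip
#'   edge is bounded by the chord sagitta, well below voxel size at
#'   millimetre steps.
#' @return object of class `centroid_graph`: `nodes` tibble
#'   (`id, x, y, z, slice, area`), `edges` tibble (`from, to, weight`),
#'   `start_node`, `end_node`.
#' @export
cross_section_centroids <- function(mesh, start, end, step = 1, max_steps = NULL,
                                    max_skip = 6L, guide = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  bb_lo <- apply(mesh$vertices, 2, min) - 5
  bb_hi <- apply(mesh$vertices, 2, max) + 5
  for (seed in list(start, end)) {
    if (any(seed < bb_lo) || any(seed > bb_hi)) {
      stop("seed outside the mesh bounding volume")
    }
  }
  max_steps <- max_steps %||% ceiling((4 * sqrt(sum((end - start)^2)) + 60) / step)
  nodes <- list(); slice_id <- 0L
  if (!is.null(guide)) {
    # guided slicing: planes at uniform arc steps of a previously extracted
    # path, normals from its tangents (near-orthogonal sections everywhere)
    gcl <- resample_centerline(guide, step)
    r_run <- NA_real_
    for (k in seq_len(nrow(gcl$points))) {
      cons <- slice_mesh(mesh, gcl$points[k, ], gcl$tangents[k, ])
      if (length(cons) == 0L) next
      cents <- lapply(cons, contour_centroid, normal = gcl$tangents[k, ],
                      r_prior = if (is.finite(r_run)) r_run else NULL)
      slice_id <- slice_id + 1L
      cmat <- t(vapply(cents, function(cc) cc$centroid, numeric(3)))
      areas <- vapply(cents, function(cc) cc$area, numeric(1))
      nodes[[slice_id]] <- cbind(cmat, slice_id, areas)
      dd <- sqrt(rowSums(sweep(cmat, 2L, gcl$points[k, ], `-`)^2))
      nb <- which.min(dd)
      if (cents[[nb]]$circularity >= 0.97 && dd[nb] <= step) {
        r_run <- sqrt(areas[nb] / pi)
      }
    }
    if (length(nodes) == 0L) stop("no cross-section contours found along the guide path")
    return(assemble_centroid_graph(nodes, start, end, step, max_skip))
  }
  n_cur <- normalize3(end - start)
  c_cur <- start
  coast_run <- 0L; c_anchor <- start; r_run <- NA_real_
  repeat {
    if (slice_id >= max_steps) break
    p_pred <- c_cur + step * n_cur
    cons <- slice_mesh(mesh, p_pred, n_cur)
    if (length(cons) == 0L) break
    cents <- lapply(cons, contour_centroid, normal = n_cur,
                    r_prior = if (is.finite(r_run)) r_run else NULL)
    slice_id <- slice_id + 1L
    cmat <- t(vapply(cents, function(cc) cc$centroid, numeric(3)))
    areas <- vapply(cents, function(cc) cc$area, numeric(1))
    nodes[[slice_id]] <- cbind(cmat, slice_id, areas)
    dist_pred <- sqrt(rowSums(sweep(cmat, 2L, p_pred, `-`)^2))
    best <- which.min(dist_pred)
    accepted <- cmat[best, ]
    disp <- accepted - c_cur
    lateral <- disp - sum(disp * n_cur) * n_cur
    circ <- cents[[best]]$circularity
    # a merged contour at a side-branch junction is markedly non-circular:
    # coast through on the previous heading instead of steering into it
    # (oblique clean cuts are ellipses with circularity near 1)
    gate <- (2 + 0.4 * coast_run) * step   # heading drift grows while coasting
    clean <- circ >= 0.95 && dist_pred[best] <= gate &&
      sqrt(sum(lateral^2)) <= gate && sqrt(sum(disp^2)) > 1e-9
    if (clean) {
      # heading from the chord between consecutive accepted centroids, so a
      # lateral recovery after coasting is spread over the coasted distance
      step_dir <- accepted - c_anchor
      if (sqrt(sum(step_dir^2)) > 1e-9) n_cur <- normalize3(step_dir)
      c_anchor <- accepted
      c_cur <- accepted
      coast_run <- 0L
      if (circ >= 0.97) r_run <- sqrt(cents[[best]]$area / pi)
    } else {
      if (coast_run >= 10L) break
      c_cur <- p_pred
      coast_run <- coast_run + 1L
    }
    if (sum((c_cur - end) * n_cur) > 0 ||
        sqrt(sum((c_cur - end)^2)) < 0.75 * step) break
  }
  if (length(nodes) == 0L) stop("no cross-section contours found between the seeds")
  assemble_centroid_graph(nodes, start, end, step, max_skip)
}

assemble_centroid_graph <- function(nodes, start, end, step, max_skip) {
  nm <- do.call(rbind, nodes)
  nodes_tb <- tibble::tibble(id = seq_len(nrow(nm)), x = nm[, 1], y = nm[, 2],
                             z = nm[, 3], slice = as.integer(nm[, 4]),
                             area = nm[, 5])
  edges <- list()
  n_slices <- max(nodes_tb$slice)
  for (k in seq_len(n_slices - 1L)) {
    a <- which(nodes_tb$slice == k)
    for (dk in seq_len(min(max_skip, n_slices - k))) {
      b <- which(nodes_tb$slice == k + dk)
      if (length(a) == 0L || length(b) == 0L) next
      grid <- expand.grid(from = a, to = b)
      w <- sqrt((nodes_tb$x[grid$from] - nodes_tb$x[grid$to])^2 +
                  (nodes_tb$y[grid$from] - nodes_tb$y[grid$to])^2 +
                  (nodes_tb$z[grid$from] - nodes_tb$z[grid$to])^2)
      edges[[length(edges) + 1L]] <- cbind(grid$from, grid$to, w)
    }
  }
  em <- do.call(rbind, edges)
  if (is.null(em)) em <- matrix(0, 0, 3)
  edges_tb <- tibble::tibble(from = as.integer(em[, 1]), to = as.integer(em[, 2]),
                             weight = pmax(em[, 3], 1e-9))
  snap <- function(seed, what) {
    dd <- sqrt((nodes_tb$x - seed[1])^2 + (nodes_tb$y - seed[2])^2 +
                 (nodes_tb$z - seed[3])^2)
    i <- which.min(dd)
    if (dd[i] > 5) stop(sprintf("no centroid within 5 mm of the %s seed", what))
    i
  }
  structure(list(nodes = nodes_tb, edges = edges_tb,
                 start_node = snap(start, "start"), end_node = snap(end, "end"),
                 step = step),
            class = "centroid_graph")
}

#' @export
print.centroid_graph <- function(x, ...) {
  cat(sprintf("<centroid_graph> %d centroids over %d slices, %d edges\n",
              nrow(x$nodes), max(x$nodes$slice), nrow(x$edges)))
  invisible(x)
}

# ---- centerline -------------------------------------------------------------

#' Centerline object
#'
#' Ordered 3D points with unit tangents and cumulative arc length. Tangents
#' use a forward difference at the first point, central differences
#' (`a_(i+1) - a_(i-1)`) in the interior and a backward difference at the
#' last point, all normalized; on a straight line every tangent is the same
#' direction. Consecutive duplicate points are dropped.
#'
#' @param points n x 3 matrix of world-mm coordinates.
#' @return object of class `centerline` with `points`, `tangents`,
#'   `arc_length`.
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L)
  keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > 1e-16)
  points <- points[keep, , drop = FALSE]
  n <- nrow(points)
  if (n < 2L) stop("centerline needs at least 2 distinct points")
  tg <- matrix(0, n, 3)
  tg[1, ] <- points[2, ] - points[1, ]
  if (n > 2L) tg[2:(n - 1), ] <- points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  tg <- tg / sqrt(rowSums(tg^2))
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] - points[-n, , drop = FALSE])^2))
  structure(list(points = points, tangents = tg,
                 arc_length = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.4g mm\n",
              nrow(x$points), max(x$arc_length)))
  invisible(x)
}

#' Dijkstra shortest-path centerline through the centroid graph
#'
#' Finds the minimum-total-Euclidean-length path from the snapped start node
#' to the snapped end node (branch-contour centroids lengthen any route
#' through them, so the path naturally avoids side branches) and turns the
#' node sequence into a [centerline()]. Optional Laplacian smoothing
#' (3-point moving average, 2 passes, endpoints fixed) is applied after path
#' selection and is off by default so deviation statistics refer to the raw
#' path.
#'
#' @param graph a [cross_section_centroids()] result.
#' @param smooth apply the smoothing passes?
#' @return a [centerline()].
#' @export
shortest_path_centerline <- function(graph, smooth = FALSE) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(graph$edges[, c("from", "to")]))))
    igraph::E(g)$weight <- graph$edges$weight
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = graph$start_node, to = graph$end_node,
                           weights = igraph::E(g)$weight, output = "vpath"))
  path <- as.integer(sp$vpath[[1]])
  if (length(path) < 2L) {
    comp <- igraph::components(g)
    stop(sprintf(
      "start and end seeds are not connected in the centroid graph (components of sizes %s)",
      paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))
  }
  pts <- as.matrix(graph$nodes[path, c("x", "y", "z")])
  if (smooth) {
    for (pass in 1:2) {
      n <- nrow(pts)
      if (n >= 3L) {
        inner <- (pts[1:(n - 2), ] + pts[2:(n - 1), ] + pts[3:n, ]) / 3
        pts[2:(n - 1), ] <- inner
      }
    }
  }
  centerline(pts)
}

#' Extract the centerline of a vessel-of-interest mask
#'
#' Convenience wrapper chaining [build_mesh()], [cross_section_centroids()]
#' and [shortest_path_centerline()].
#'
#' @param voi_mask logical [vol3d()] vessel-of-interest mask.
#' @param start,end seed points (world mm).
#' @param step slice spacing (mm).
#' @param smooth smooth the final path?
#' @param smooth_sigma mesh pre-smoothing (voxels), see [build_mesh()].
#' @param refine run a second, guided slicing pass with planes orthogonal
#'   to the first-pass path (reduces junction contour merging).
#' @return a [centerline()].
#' @export
extract_centerline <- function(voi_mask, start, end, step = 1, smooth = FALSE,
                               smooth_sigma = 1, refine = TRUE) {
  mesh <- build_mesh(voi_mask, smooth_sigma = smooth_sigma)
  graph <- cross_section_centroids(mesh, start, end, step = step)
  cl <- shortest_path_centerline(graph, smooth = smooth)
  if (refine) {
    # second pass: re-slice with planes orthogonal to the first-pass path,
    # which minimizes contour merging at side-branch junctions
    graph2 <- tryCatch(
      cross_section_centroids(mesh, start, end, step = step, guide = cl),
      error = function(e) NULL)
    if (!is.null(graph2)) {
      cl2 <- tryCatch(shortest_path_centerline(graph2, smooth = smooth),
                      error = function(e) NULL)
      if (!is.null(cl2)) cl <- cl2
    }
  }
  cl
}

#' Point-to-curve deviation between centerlines
#'
#' For every point of the extracted centerline, the exact distance to the
#' reference polyline (point-to-segment, equivalent to a densely resampled
#' reference); reports mean, standard deviation and maximum.
#'
#' @param extracted a [centerline()] (or n x 3 matrix).
#' @param reference a [centerline()] or n x 3 matrix of reference points.
#' @return object of class `deviation_summary`: `mean`, `sd`, `max` (mm) and
#'   the per-point `distances`.
#' @export
centerline_deviation <- function(extracted, reference) {
  P <- if (inherits(extracted, "centerline")) extracted$points else as.matrix(extracted)
  Q <- if (inherits(reference, "centerline")) reference$points else as.matrix(reference)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("empty centerline")
  if (nrow(Q) == 1L) {
    d <- sqrt(rowSums(sweep(P, 2L, Q[1, ], `-`)^2))
  } else {
    A <- Q[-nrow(Q), , drop = FALSE]
    B <- Q[-1, , drop = FALSE]
    AB <- B - A
    len2 <- pmax(rowSums(AB^2), 1e-300)
    d <- vapply(seq_len(nrow(P)), function(i) {
      AP <- sweep(-A, 2L, P[i, ], `+`)      # P - A
      tt <- pmin(pmax(rowSums(AP * AB) / len2, 0), 1)
      dd <- AP - AB * tt
      sqrt(min(rowSums(dd^2)))
    }, numeric(1))
  }
  structure(list(mean = mean(d), sd = stats::sd(d), max = max(d), distances = d,
                 n = length(d)),
            class = "deviation_summary")
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf("<deviation_summary> mean %.3f +/- %.3f mm, max %.3f mm (n = %d points)\n",
              x$mean, x$sd, x$max, x$n))
  invisible(x)
}

#' Largest inscribed sphere radius along a centerline
#'
#' Distance from each centerline point to the nearest wall voxel centre: a
#' diagnostic for how close the path runs to the medial axis (the centerline
#' of an ideal tube has inscribed radius equal to the lumen radius).
#'
#' @param cl a [centerline()].
#' @param wall_mask logical wall mask from [extract_wall()].
#' @return numeric vector of radii (mm), one per centerline point.
#' @export
inscribed_radius <- function(cl, wall_mask) {
  w <- which(wall_mask, arr.ind = TRUE)
  wpts <- voxel_to_world(w, vol_spacing(wall_mask), vol_origin(wall_mask))
  vapply(seq_len(nrow(cl$points)), function(i) {
    sqrt(min(rowSums(sweep(wpts, 2L, cl$points[i, ], `-`)^2)))
  }, numeric(1))
}
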