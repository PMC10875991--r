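#' @importFrom stats rnorm runif sd approx median
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach voxel geometry to a 3D array
#'
#' Volumes in this package are plain 3D arrays (x, y, z; x fastest) carrying
#' `spacing` (mm per voxel along each axis) and `origin` (world coordinate of
#' the centre of voxel `[1, 1, 1]`, mm) as attributes. World coordinates are
#' `origin + (index - 1) * spacing`.
#'
#' @param values 3D array (logical, integer or double).
#' @param spacing numeric length 3, mm.
#' @param origin numeric length 3, mm.
#' @return the array with `spacing`/`origin` attributes set.
#' @export
vol3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  attr(values, "spacing") <- as.numeric(spacing)
  attr(values, "origin") <- as.numeric(origin)
  values
}

#' @rdname vol3d
#' @param x a volume created with [vol3d()] (or any array).
#' @export
vol_spacing <- function(x) attr(x, "spacing") %||% c(1, 1, 1)

#' @rdname vol3d
#' @export
vol_origin <- function(x) attr(x, "origin") %||% c(0, 0, 0)

voxel_to_world <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2L, spacing, `*`), 2L, origin, `+`)
}

world_to_voxel <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2L, origin, `-`), 2L, spacing, `/`) + 1
}

# out[i] = m[i - s] (zero/FALSE fill outside)
shift3 <- function(m, s, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- lapply(1:3, function(k) seq_len(d[k]) - s[k])
  ok <- lapply(1:3, function(k) src[[k]] >= 1L & src[[k]] <= d[k])
  if (!all(vapply(ok, any, logical(1)))) return(out)
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    m[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

# 6-neighbourhood binary erosion; voxels on the array border erode away
erode6 <- function(m) {
  m & shift3(m, c(1, 0, 0)) & shift3(m, c(-1, 0, 0)) &
    shift3(m, c(0, 1, 0)) & shift3(m, c(0, -1, 0)) &
    shift3(m, c(0, 0, 1)) & shift3(m, c(0, 0, -1))
}

# binary dilation by a metric ball of `radius_mm`
dilate_ball <- function(m, radius_mm, spacing = vol_spacing(m)) {
  if (radius_mm <= 0 || !any(m)) return(m)
  h <- pmax(0L, ceiling(radius_mm / spacing))
  offs <- as.matrix(expand.grid(-h[1]:h[1], -h[2]:h[2], -h[3]:h[3]))
  dist <- sqrt(colSums((t(offs) * spacing)^2))
  offs <- offs[dist <= radius_mm, , drop = FALSE]
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (r in seq_len(nrow(offs))) {
    p <- idx
    p[, 1] <- p[, 1] + offs[r, 1]
    p[, 2] <- p[, 2] + offs[r, 2]
    p[, 3] <- p[, 3] + offs[r, 3]
    keep <- p[, 1] >= 1L & p[, 1] <= d[1] & p[, 2] >= 1L & p[, 2] <= d[2] &
      p[, 3] >= 1L & p[, 3] <= d[3]
    out[p[keep, , drop = FALSE]] <- TRUE
  }
  attributes(out) <- attributes(m)
  out
}

# 6-connected component labelling via igraph; labels sorted by size (1 = largest)
label_components <- function(mask) {
  d <- dim(mask)
  n <- sum(mask)
  labels <- array(0L, d)
  if (n == 0L) return(list(labels = labels, sizes = integer(0)))
  id <- array(0L, d)
  id[mask] <- seq_len(n)
  edges <- vector("list", 3L)
  shifts <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  for (k in 1:3) {
    both <- mask & shift3(mask, shifts[[k]])
    if (any(both)) {
      edges[[k]] <- cbind(id[both], shift3(id, shifts[[k]], fill = 0L)[both])
    }
  }
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  labels[mask] <- relabel[comp$membership]
  list(labels = labels, sizes = as.integer(comp$csize[ord]))
}

largest_component <- function(mask, warn_multiple = FALSE, what = "mask") {
  cc <- label_components(mask)
  if (length(cc$sizes) == 0L) return(mask & FALSE)
  if (warn_multiple && length(cc$sizes) > 1L) {
    warning(sprintf("%s has %d connected components; using the largest (%d voxels)",
                    what, length(cc$sizes), cc$sizes[1]), call. = FALSE)
  }
  out <- cc$labels == 1L
  attributes(out) <- attributes(mask)
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing, sigma in voxels, edge replication
smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  d <- dim(a)
  for (ax in 1:3) {
    out <- array(0, d)
    for (j in seq_along(k)) {
      s <- j - r - 1L
      idx <- pmin(pmax(seq_len(d[ax]) - s, 1L), d[ax])
      sl <- switch(ax,
                   a[idx, , , drop = FALSE],
                   a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + k[j] * sl
    }
    a <- out
  }
  a
}

# vectorized trilinear interpolation at continuous 1-based voxel coordinates
interp_trilinear <- function(vol, pts_vox, fill = NA_real_) {
  d <- dim(vol)
  n <- nrow(pts_vox)
  out <- rep(fill, n)
  x <- pts_vox[, 1]; y <- pts_vox[, 2]; z <- pts_vox[, 3]
  valid <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3] &
    is.finite(x) & is.finite(y) & is.finite(z)
  if (!any(valid)) return(out)
  x <- x[valid]; y <- y[valid]; z <- z[valid]
  i0 <- pmin(floor(x), d[1] - 1); fx <- x - i0
  j0 <- pmin(floor(y), d[2] - 1); fy <- y - j0
  k0 <- pmin(floor(z), d[3] - 1); fz <- z - k0
  if (d[1] == 1L) { i0 <- rep(1, length(x)); fx <- 0 }
  if (d[2] == 1L) { j0 <- rep(1, length(y)); fy <- 0 }
  if (d[3] == 1L) { k0 <- rep(1, length(z)); fz <- 0 }
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (i0) + (j0 - 1) * n1 + (k0 - 1) * n12
  dx <- if (d[1] > 1L) 1 else 0
  dy <- if (d[2] > 1L) n1 else 0
  dz <- if (d[3] > 1L) n12 else 0
  v <- vol
  val <-
    v[base]                 * (1 - fx) * (1 - fy) * (1 - fz) +
    v[base + dx]            * fx       * (1 - fy) * (1 - fz) +
    v[base + dy]            * (1 - fx) * fy       * (1 - fz) +
    v[base + dx + dy]       * fx       * fy       * (1 - fz) +
    v[base + dz]            * (1 - fx) * (1 - fy) * fz +
    v[base + dx + dz]       * fx       * (1 - fy) * fz +
    v[base + dy + dz]       * (1 - fx) * fy       * fz +
    v[base + dx + dy + dz]  * fx       * fy       * fz
  out[valid] <- val
  out
}

# Otsu's threshold on a numeric vector (maximum between-class variance)
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) return(suppressWarnings(max(x, -Inf)))
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-nbins])
  (mids[k] + mids[k + 1]) / 2
}

normalize3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal in-plane basis (e1, e2) for a unit normal
plane_basis <- function(normal) {
  ref <- if (abs(normal[1]) <= abs(normal[2]) && abs(normal[1]) <= abs(normal[3])) {
    c(1, 0, 0)
  } else if (abs(normal[2]) <= abs(normal[3])) c(0, 1, 0) else c(0, 0, 1)
  e1 <- normalize3(cross3(ref, normal))
  e2 <- cross3(normal, e1)
  list(e1 = e1, e2 = e2)
}
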