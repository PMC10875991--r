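#' Time-to-peak from a filtered derivative curve
#'
#' The peak of the smoothed TAC is where its derivative crosses zero from
#' above. With `t_(I+1)` the first sample time at which the derivative is no
#' longer positive after its maximum (the steepest uptake; anchoring the
#' search there makes the crossing immune to sign flutter of the flat
#' pre-bolus baseline under noise, and is identical to the first sign change
#' on noise-free curves) and `t_I` the sample before it, the crossing is
#' located by linear interpolation:
#' `a = (v'_(I+1) - v'_I) / (t_(I+1) - t_I)`, `b = v'_(I+1) - a t_(I+1)`,
#' `t_ttp = -b / a`. The estimate is invariant to TAC amplitude scaling
#' (`a` and `b` scale together). When the derivative never turns non-positive
#' after being positive (e.g. late-filling vessels truncated by scan end) the
#' result is `NaN`, not an error; a flat crossing (`a = 0`) returns
#' `t_(I+1)`, the limit of the interpolation as the slope vanishes.
#'
#' @param vprime numeric derivative curve (one value per frame).
#' @param times frame times (s), same length.
#' @return `t_ttp` in seconds, or `NaN` when undefined.
#' @examples
#' compute_ttp(c(2, 1, -1, -2), times = 1:4)  # symmetric crossing -> 2.5
#' @export
compute_ttp <- function(vprime, times) {
  stopifnot(length(vprime) == length(times))
  ipk <- which.max(vprime)
  if (!is.finite(vprime[ipk]) || vprime[ipk] <= 0) return(NaN)
  cand <- which(vprime <= 0 & seq_along(vprime) > ipk)
  if (length(cand) == 0) return(NaN)
  i1 <- cand[1]
  i0 <- i1 - 1L
  a <- (vprime[i1] - vprime[i0]) / (times[i1] - times[i0])
  if (a == 0) return(times[i1])
  b <- vprime[i1] - a * times[i1]
  -b / a
}

#' Per-voxel time-to-peak map over a vessel mask
#'
#' Filters every masked voxel's TAC with the derivative-of-Gaussian kernel
#' and applies [compute_ttp()]. Voxels outside the mask, or with no
#' defined crossing, carry `NaN`. The per-voxel interpolation coefficients
#' `a` and `b` are returned alongside.
#'
#' @param series a (skull-stripped) [ctp_series()].
#' @param vessel_mask logical 3D mask on the series grid.
#' @param filter a [dog_filter()].
#' @return object of class `ttp_map`: `ttp`, `a`, `b` ([vol3d()] arrays,
#'   `NaN` where undefined), `times`, and the mask used.
#' @export
compute_ttp_map <- function(series, vessel_mask, filter = dog_filter()) {
  stopifnot(inherits(series, "ctp_series"))
  if (!all(dim(vessel_mask) == dim(series$values)[1:3])) {
    stop("vessel mask grid does not match the series grid")
  }
  if (!any(vessel_mask)) stop("vessel mask is empty")
  lin <- which(vessel_mask)
  nvox <- prod(dim(series$values)[1:3])
  T_ <- n_frames(series)
  V <- matrix(series$values, ncol = T_)[lin, , drop = FALSE]
  vp <- filter_tac_matrix(V, filter$taps)
  tt <- series$times

  ipk <- max.col(vp, ties.method = "first")
  pk_pos <- vp[cbind(seq_len(nrow(vp)), ipk)] > 0
  cand <- (vp <= 0) & (col(vp) > ipk) & pk_pos
  has <- rowSums(cand) > 0
  i1 <- rep(NA_integer_, nrow(vp))
  i1[has] <- max.col(cand[has, , drop = FALSE], ties.method = "first")

  ttp_v <- rep(NaN, nrow(vp))
  a_v <- rep(NaN, nrow(vp))
  b_v <- rep(NaN, nrow(vp))
  if (any(has)) {
    r <- which(has)
    j1 <- i1[r]; j0 <- j1 - 1L
    v1 <- vp[cbind(r, j1)]; v0 <- vp[cbind(r, j0)]
    a <- (v1 - v0) / (tt[j1] - tt[j0])
    b <- v1 - a * tt[j1]
    t_est <- ifelse(a == 0, tt[j1], -b / a)
    ttp_v[r] <- t_est
    a_v[r] <- a
    b_v[r] <- b
  }
  mk <- function(vals) {
    arr <- array(NaN, dim(series$values)[1:3])
    arr[lin] <- vals
    vol3d(arr, spacing = series$spacing, origin = series$origin)
  }
  structure(list(ttp = mk(ttp_v), a = mk(a_v), b = mk(b_v),
                 times = tt, mask = vessel_mask),
            class = "ttp_map")
}

#' Artery/vein threshold at the TTP histogram valley
#'
#' Builds a histogram of the defined TTP values, detects its two
#' highest-prominence peaks, and takes the centre of the minimum-count bin
#' strictly between them as the separation threshold `v_ttp` (contrast
#' reaches arteries statistically earlier than veins, so the arterial and
#' venous modes flank the valley). Ties in the valley are broken toward the
#' lower TTP.
#'
#' @param ttpmap a [compute_ttp_map()] result (or a plain numeric vector of
#'   TTP values).
#' @param n_bins histogram bins; default 4 bins per frame interval.
#' @return object of class `av_threshold`: `v_ttp` (s), the `histogram`
#'   tibble (`low`, `high`, `mid`, `count`), `peak_bins`, `valley_bin`.
#' @export
find_valley_threshold <- function(ttpmap, n_bins = NULL) {
  if (inherits(ttpmap, "ttp_map")) {
    vals <- ttpmap$ttp[is.finite(ttpmap$ttp)]
    n_bins <- n_bins %||% (4L * (length(ttpmap$times) - 1L))
  } else {
    vals <- ttpmap[is.finite(ttpmap)]
    n_bins <- n_bins %||% 64L
  }
  if (length(vals) < 2L || diff(range(vals)) == 0) {
    stop("TTP histogram is degenerate; supply the artery/vein threshold manually")
  }
  br <- seq(min(vals), max(vals), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(vals, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2

  loc_max <- which(vapply(seq_len(n_bins), function(i) {
    left <- if (i == 1L) -Inf else counts[i - 1L]
    right <- if (i == n_bins) -Inf else counts[i + 1L]
    counts[i] > 0 && counts[i] > left && counts[i] >= right
  }, logical(1)))
  if (length(loc_max) < 2L) {
    stop("TTP histogram appears unimodal; supply the artery/vein threshold manually")
  }
  prom <- vapply(loc_max, function(p) {
    h <- counts[p]
    higher_l <- which(counts[seq_len(p - 1L)] > h)
    higher_r <- which(counts[seq_len(n_bins) > p] > h) + p
    saddle <- function(rng) if (length(rng) == 0) NA_real_ else min(counts[rng])
    s_l <- if (length(higher_l) > 0) saddle((max(higher_l) + 1L):(p - 1L)) else NA_real_
    s_r <- if (length(higher_r) > 0) saddle((p + 1L):(min(higher_r) - 1L)) else NA_real_
    key <- suppressWarnings(max(s_l, s_r, na.rm = TRUE))
    if (!is.finite(key)) key <- min(counts)
    h - key
  }, numeric(1))
  ord <- order(prom, counts[loc_max], -loc_max, decreasing = TRUE)
  peaks <- sort(loc_max[ord[1:2]])
  if (peaks[2] - peaks[1] < 2L) {
    stop("the two TTP modes are not separated by any bin; increase `n_bins` or supply a threshold")
  }
  between <- (peaks[1] + 1L):(peaks[2] - 1L)
  valley <- between[which.min(counts[between])]   # which.min: lowest index on ties
  structure(list(
    v_ttp = mids[valley],
    histogram = tibble::tibble(low = br[-length(br)], high = br[-1],
                               mid = mids, count = counts),
    peak_bins = peaks, valley_bin = valley, n_bins = n_bins),
    class = "av_threshold")
}

#' @export
print.av_threshold <- function(x, ...) {
  cat(sprintf("<av_threshold> v_ttp = %.4g s (valley bin %d between peak bins %d and %d)\n",
              x$v_ttp, x$valley_bin, x$peak_bins[1], x$peak_bins[2]))
  invisible(x)
}

#' Split the vessel mask into arterial and venous volumes
#'
#' Arteries are the vessel voxels with `TTP <= v_ttp`, veins those with
#' `TTP > v_ttp`. Voxels whose TTP is undefined (derivative never turned
#' non-positive, i.e. still filling at scan end) are assigned to the veins,
#' the latest possible arrival. The two masks are disjoint and their union
#' is the vessel mask.
#'
#' @param ttpmap a [compute_ttp_map()] result.
#' @param vessel_mask logical 3D vessel mask.
#' @param threshold an [find_valley_threshold()] result or a numeric
#'   threshold in seconds.
#' @return list with logical [vol3d()] masks `artery` and `vein` and the
#'   numeric `v_ttp` used.
#' @export
separate_arteries_veins <- function(ttpmap, vessel_mask, threshold) {
  v <- if (inherits(threshold, "av_threshold")) threshold$v_ttp else as.numeric(threshold)
  if (!is.finite(v)) stop("`threshold` must be finite")
  ttp <- ttpmap$ttp
  defined <- is.finite(ttp)
  artery <- vessel_mask & defined & (ttp <= v)
  vein <- vessel_mask & !artery
  attrs <- attributes(ttp)[c("dim", "spacing", "origin")]
  attributes(artery) <- attrs
  attributes(vein) <- attrs
  list(artery = artery, vein = vein, v_ttp = v)
}

#' Arteriographic / venographic HU volumes
#'
#' Temporal maximum-intensity projection of the series inside each mask:
#' the CTA shows the arterial mask at its peak enhancement, the CTV the
#' venous mask. Voxels outside the mask carry the `background` sentinel.
#'
#' @param series a [ctp_series()].
#' @param av result of [separate_arteries_veins()].
#' @param background HU sentinel outside the masks.
#' @return list of [vol3d()] volumes `cta` and `ctv`.
#' @export
angiographic_volumes <- function(series, av, background = -1024) {
  tmip <- series$values[, , , 1, drop = TRUE]
  for (f in seq_len(n_frames(series))[-1]) {
    tmip <- pmax(tmip, series$values[, , , f, drop = TRUE])
  }
  mk <- function(mask) {
    out <- array(background, dim(mask))
    out[mask] <- tmip[mask]
    vol3d(out, spacing = series$spacing, origin = series$origin)
  }
  list(cta = mk(av$artery), ctv = mk(av$vein))
}
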