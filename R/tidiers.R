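#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for pipeline results
#'
#' `tidy()` returns the tabular content of a result as a tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x a `centerline`, `av_threshold`, `deviation_summary`,
#'   `caliber_profile`, `centerline_validation` or `caliber_validation`
#'   object.
#' @param ... unused.
#' @name ctpangio-tidiers
NULL

#' @rdname ctpangio-tidiers
#' @export
tidy.centerline <- function(x, ...) {
  p <- x$points
  tg <- x$tangents
  tibble::tibble(s = x$arc_length, x = p[, 1], y = p[, 2], z = p[, 3],
                 tx = tg[, 1], ty = tg[, 2], tz = tg[, 3])
}

#' @rdname ctpangio-tidiers
#' @export
glance.centerline <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points), length_mm = max(x$arc_length))
}

#' @rdname ctpangio-tidiers
#' @export
tidy.av_threshold <- function(x, ...) x$histogram

#' @rdname ctpangio-tidiers
#' @export
glance.av_threshold <- function(x, ...) {
  tibble::tibble(v_ttp = x$v_ttp, n_bins = x$n_bins,
                 peak_low = x$histogram$mid[x$peak_bins[1]],
                 peak_high = x$histogram$mid[x$peak_bins[2]])
}

#' @rdname ctpangio-tidiers
#' @export
tidy.deviation_summary <- function(x, ...) {
  tibble::tibble(point = seq_along(x$distances), distance = x$distances)
}

#' @rdname ctpangio-tidiers
#' @export
glance.deviation_summary <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, max = x$max, n_points = x$n)
}

#' @rdname ctpangio-tidiers
#' @export
tidy.caliber_profile <- function(x, ...) x$profile

#' @rdname ctpangio-tidiers
#' @export
glance.caliber_profile <- function(x, ...) {
  tibble::tibble(median_area = x$median_area, min_area_s = x$min_area_s,
                 max_area_s = x$max_area_s,
                 n_stenosis_intervals = length(x$stenosis_intervals),
                 n_dilation_intervals = length(x$dilation_intervals))
}

#' @rdname ctpangio-tidiers
#' @export
tidy.centerline_validation <- function(x, ...) x$report

#' @rdname ctpangio-tidiers
#' @export
glance.centerline_validation <- function(x, ...) {
  tibble::tibble(mean_mm = x$grand_mean, sd_mm = x$grand_sd,
                 max_mm = x$grand_max, n_points = x$n_points,
                 n_phantoms = nrow(x$report))
}

#' @rdname ctpangio-tidiers
#' @export
tidy.caliber_validation <- function(x, ...) x$report

#' @rdname ctpangio-tidiers
#' @export
glance.caliber_validation <- function(x, ...) {
  tibble::tibble(accuracy_pct = x$accuracy, n_phantoms = x$n_phantoms)
}
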