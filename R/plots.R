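#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_vline
#'   geom_point geom_rect labs theme_minimal facet_wrap
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot the TTP histogram with its artery/vein valley
#'
#' @param object an [find_valley_threshold()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.av_threshold <- function(object, ...) {
  h <- object$histogram
  ggplot(h, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = diff(h$mid[1:2]), fill = "grey55") +
    geom_vline(xintercept = object$v_ttp, colour = "red", linetype = 2) +
    geom_point(data = h[object$peak_bins, ], colour = "steelblue", size = 2) +
    labs(x = "time to peak (s)", y = "voxels",
         title = sprintf("TTP histogram, valley threshold %.2f s", object$v_ttp)) +
    theme_minimal()
}

#' Plot a centerline as its three axis projections
#'
#' @param object a [centerline()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.centerline <- function(object, ...) {
  td <- tidy(object)
  long <- dplyr::bind_rows(
    tibble::tibble(s = td$s, value = td$x, coord = "x"),
    tibble::tibble(s = td$s, value = td$y, coord = "y"),
    tibble::tibble(s = td$s, value = td$z, coord = "z"))
  ggplot(long, aes(x = .data$s, y = .data$value)) +
    geom_line() +
    facet_wrap(~coord, scales = "free_y") +
    labs(x = "arc length (mm)", y = "coordinate (mm)") +
    theme_minimal()
}

#' Plot a straightened vessel's caliber profile
#'
#' Lumen cross-section area against arc length with flagged stenotic and
#' dilated intervals shaded.
#'
#' @param object an [assess_caliber_profile()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.caliber_profile <- function(object, ...) {
  p <- object$profile
  iv <- function(lst, what) {
    if (length(lst) == 0) return(NULL)
    tibble::tibble(lo = vapply(lst, `[`, numeric(1), 1),
                   hi = vapply(lst, `[`, numeric(1), 2), flag = what)
  }
  shade <- dplyr::bind_rows(iv(object$stenosis_intervals, "stenosis"),
                            iv(object$dilation_intervals, "dilation"))
  g <- ggplot(p, aes(x = .data$s, y = .data$area))
  if (!is.null(shade) && nrow(shade) > 0) {
    g <- g + geom_rect(data = shade, inherit.aes = FALSE,
                       aes(xmin = .data$lo, xmax = .data$hi,
                           ymin = -Inf, ymax = Inf, fill = .data$flag),
                       alpha = 0.25)
  }
  g + geom_line() +
    labs(x = "arc length (mm)", y = expression(area ~ (mm^2)),
         fill = NULL,
         title = "Straightened-vessel caliber profile") +
    theme_minimal()
}

#' Plot per-phantom centerline deviations by branch count
#'
#' @param object a [validate_centerline_accuracy()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.centerline_validation <- function(object, ...) {
  r <- object$report
  ggplot(r, aes(x = factor(.data$n_branches), y = .data$max)) +
    geom_point(position = ggplot2::position_jitter(width = 0.1, height = 0),
               alpha = 0.7) +
    geom_point(aes(y = .data$mean), colour = "steelblue", alpha = 0.7,
               position = ggplot2::position_jitter(width = 0.1, height = 0)) +
    labs(x = "side branches", y = "deviation (mm)",
         title = "Centerline deviation vs analytic axis",
         subtitle = "blue: per-phantom mean, black: per-phantom max") +
    theme_minimal()
}
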