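#' Pipeline configuration
#'
#' All defaults match the printed processing parameters: 155 HU skull
#' threshold, derivative-of-Gaussian sigma 3 with a 1 x 5 kernel; thresholds
#' that the pipeline can choose automatically (`fg_threshold`, `v_ttp`)
#' default to `NULL` and the chosen values are recorded in the run manifest
#' so any run can be replayed with explicit numbers. The configuration
#' round-trips losslessly through YAML.
#'
#' @param skull_threshold_hu skull mask threshold (HU).
#' @param skull_dilate_mm dilation margin on the skull mask (mm).
#' @param dog_sigma,dog_ksize derivative-of-Gaussian parameters
#'   (frame-index units, taps).
#' @param fg_threshold explicit FG threshold or `NULL` (automatic Otsu).
#' @param ttp_bins TTP histogram bins or `NULL` (4 per frame interval).
#' @param v_ttp explicit artery/vein threshold (s) or `NULL` (histogram
#'   valley).
#' @param centerline_step slice spacing for centroid extraction (mm).
#' @param half_size_mm,in_plane_spacing,straighten_step straightening plane
#'   geometry (mm).
#' @param straighten_frames `"mip"`, `"all"` or a frame index.
#' @param seed RNG seed recorded with the run (the pipeline stages
#'   themselves are deterministic; randomness lives only in the phantom
#'   generators).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(skull_threshold_hu = 155, skull_dilate_mm = 0,
                            dog_sigma = 3, dog_ksize = 5,
                            fg_threshold = NULL, ttp_bins = NULL, v_ttp = NULL,
                            centerline_step = 1, half_size_mm = 6,
                            in_plane_spacing = 0.5, straighten_step = 0.5,
                            straighten_frames = "mip", seed = 1L) {
  structure(list(schema = "ctpangio-config-1",
                 skull_threshold_hu = skull_threshold_hu,
                 skull_dilate_mm = skull_dilate_mm,
                 dog_sigma = dog_sigma, dog_ksize = dog_ksize,
                 fg_threshold = fg_threshold, ttp_bins = ttp_bins,
                 v_ttp = v_ttp, centerline_step = centerline_step,
                 half_size_mm = half_size_mm,
                 in_plane_spacing = in_plane_spacing,
                 straighten_step = straighten_step,
                 straighten_frames = straighten_frames, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$schema, "ctpangio-config-1")) {
    stop("unrecognized config schema: ", raw$schema %||% "<missing>")
  }
  cfg <- pipeline_config()
  for (nm in setdiff(names(cfg), "schema")) {
    if (nm %in% names(raw)) cfg[nm] <- list(raw[[nm]])   # keeps NULL entries
  }
  cfg
}

run_stage <- function(name, expr, verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Run the full angiographic pipeline
#'
#' Executes skull stripping, FG vessel segmentation, TTP artery/vein
#' separation, and — when a vessel-of-interest mask and seed pair are given
#' — centerline extraction and straightening. Every stage is deterministic;
#' the returned manifest records the configuration and every automatically
#' chosen threshold so a run is fully replayable.
#'
#' @param series a [ctp_series()].
#' @param voi_mask optional logical vessel-of-interest mask (same grid).
#' @param seeds optional `list(start =, end =)` world-mm seed points.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, CTA/CTV/TTP NIfTI volumes,
#'   the centerline JSON and the straightened volume are written there along
#'   with a JSON manifest.
#' @param verbose log stage timings?
#' @return object of class `pipeline_run`: the stage outputs
#'   (`skull_mask`, `stripped`, `fg`, `vessels`, `ttp`, `av_threshold`,
#'   `artery`, `vein`, `cta`, `ctv`, and when a VOI is supplied
#'   `centerline`, `straightened`), plus `manifest`.
#' @export
run_pipeline <- function(series, voi_mask = NULL, seeds = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(series, "ctp_series"))
  filt <- dog_filter(config$dog_sigma, config$dog_ksize)
  skull <- run_stage("skull-mask",
                     compute_skull_mask(series, config$skull_threshold_hu), verbose)
  stripped <- run_stage("strip",
                        strip_skull(series, skull, config$skull_dilate_mm), verbose)
  fg <- run_stage("fg", compute_fg(stripped, filt), verbose)
  vessels <- run_stage("vesselseg",
                       segment_vessels(fg, config$fg_threshold), verbose)
  ttp <- run_stage("ttp", compute_ttp_map(stripped, vessels, filt), verbose)
  thr <- run_stage("valley", {
    if (!is.null(config$v_ttp)) config$v_ttp
    else find_valley_threshold(ttp, config$ttp_bins)
  }, verbose)
  av <- run_stage("avsep", separate_arteries_veins(ttp, vessels, thr), verbose)
  angio <- angiographic_volumes(stripped, av)
  out <- list(skull_mask = skull, stripped = stripped, fg = fg,
              vessels = vessels, ttp = ttp, av_threshold = thr,
              artery = av$artery, vein = av$vein,
              cta = angio$cta, ctv = angio$ctv)
  manifest <- list(
    config = unclass(config),
    chosen = list(fg_threshold = attr(vessels, "threshold"),
                  v_ttp = av$v_ttp),
    stages = c("strip", "vesselseg", "avsep"),
    version = as.character(utils::packageVersion("ctpangio")))
  if (is.null(voi_mask)) {
    message("no vessel-of-interest mask supplied; stopping after artery/vein separation")
  } else {
    if (is.null(seeds)) stop("`seeds` (start/end points) are required with a VOI mask")
    cl <- run_stage("centerline",
                    extract_centerline(voi_mask, seeds$start, seeds$end,
                                       step = config$centerline_step), verbose)
    stack <- run_stage("planes",
                       propagate_planes(cl, config$half_size_mm,
                                        config$in_plane_spacing,
                                        config$straighten_step), verbose)
    straightened <- run_stage("straighten",
                              resample_on_planes(stripped, stack,
                                                 frames = config$straighten_frames),
                              verbose)
    out$centerline <- cl
    out$straightened <- straightened
    manifest$stages <- c(manifest$stages, "centerline", "straighten")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(out$cta, file.path(out_dir, "cta.nii.gz"))
    write_volume(out$ctv, file.path(out_dir, "ctv.nii.gz"))
    write_volume(out$ttp$ttp, file.path(out_dir, "ttp.nii.gz"))
    write_volume(out$artery, file.path(out_dir, "artery_mask.nii.gz"))
    write_volume(out$vein, file.path(out_dir, "vein_mask.nii.gz"))
    if (!is.null(out$centerline)) {
      write_centerline_json(out$centerline,
                            file.path(out_dir, "centerline.json"))
      write_volume(vol3d(if (length(dim(out$straightened$values)) == 4L)
        out$straightened$values[, , , 1] else out$straightened$values,
        spacing = out$straightened$spacing),
        file.path(out_dir, "straightened.nii.gz"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out$manifest <- manifest
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat(sprintf("  FG threshold %.4g, v_ttp %.4g s\n",
              x$manifest$chosen$fg_threshold, x$manifest$chosen$v_ttp))
  cat(sprintf("  artery %d voxels, vein %d voxels\n",
              sum(x$artery), sum(x$vein)))
  invisible(x)
}

#' Write / read a centerline as JSON
#'
#' Ordered points (mm), unit tangents and cumulative arc length.
#'
#' @param cl a [centerline()].
#' @param path JSON file path.
#' @export
write_centerline_json <- function(cl, path) {
  jsonlite::write_json(
    list(points = unname(apply(cl$points, 1, c, simplify = FALSE)),
         tangents = unname(apply(cl$tangents, 1, c, simplify = FALSE)),
         arc_length = cl$arc_length),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerline_json
#' @export
read_centerline_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- raw$points
  if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
  centerline(as.matrix(pts))
}

# ---- validation suites ------------------------------------------------------

#' Centerline-accuracy validation on curved-tube phantoms
#'
#' Generates curved-tube phantoms with 0, 3 and 6 side branches
#' ([make_deviation_phantom()]), extracts each centerline between the
#' analytic endpoints, and measures point-to-curve deviations from the
#' analytic axis. Returns a per-phantom report plus pooled statistics: the
#' pooled mean/sd are over all extracted points of the suite, the maximum
#' over everything.
#'
#' @param n_per_branch phantoms per branch count.
#' @param branch_counts branch configurations to test.
#' @param seed base RNG seed; phantom `i` of branch count `b` uses a seed
#'   derived deterministically from it.
#' @param spacing rasterization spacing (mm).
#' @param step slice spacing for centroid extraction (mm).
#' @return object of class `centerline_validation`: `report` tibble
#'   (`n_branches`, `phantom`, `n_points`, `mean`, `sd`, `max`), and pooled
#'   `grand_mean`, `grand_sd`, `grand_max`, `max_by_branch`.
#' @export
validate_centerline_accuracy <- function(n_per_branch = 10,
                                         branch_counts = c(0, 3, 6),
                                         seed = 1L, spacing = 0.5, step = 1) {
  rows <- list()
  sum_d <- 0; sum_d2 <- 0; n_tot <- 0L
  for (bi in seq_along(branch_counts)) {
    bc <- branch_counts[bi]
    for (i in seq_len(n_per_branch)) {
      ph_seed <- (seed * 131L + bi * 17L + i) %% .Machine$integer.max
      ph <- make_deviation_phantom(bc, seed = ph_seed, spacing = spacing)
      cl <- extract_centerline(ph$mask, ph$seeds$start, ph$seeds$end, step = step)
      dev <- centerline_deviation(cl, ph$reference)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_branches = bc, phantom = i, n_points = dev$n,
        mean = dev$mean, sd = dev$sd, max = dev$max)
      sum_d <- sum_d + sum(dev$distances)
      sum_d2 <- sum_d2 + sum(dev$distances^2)
      n_tot <- n_tot + dev$n
    }
  }
  report <- dplyr::bind_rows(rows)
  gm <- sum_d / n_tot
  gsd <- sqrt(max(0, sum_d2 / n_tot - gm^2))
  structure(list(report = report, grand_mean = gm, grand_sd = gsd,
                 grand_max = max(report$max),
                 max_by_branch = report |>
                   dplyr::group_by(.data$n_branches) |>
                   dplyr::summarise(max = max(.data$max), .groups = "drop"),
                 n_points = n_tot),
            class = "centerline_validation")
}

#' @export
print.centerline_validation <- function(x, ...) {
  cat(sprintf("<centerline_validation> %d phantoms, %d centerline points\n",
              nrow(x$report), x$n_points))
  cat(sprintf("  deviation %.3f +/- %.3f mm (pooled), max %.3f mm\n",
              x$grand_mean, x$grand_sd, x$grand_max))
  print(x$max_by_branch)
  invisible(x)
}

#' Stenosis/dilation localization validation on straightened phantoms
#'
#' Generates tube phantoms each carrying one stenosis (radius factor 0.5)
#' and one dilation (factor 1.5) at known arc-length intervals
#' ([make_stenosis_phantom()]), extracts the centerline, straightens the
#' mask, and checks whether the minimum-area straightened slice falls inside
#' the ground-truth stenosis interval and the maximum-area slice inside the
#' dilation interval. Arc positions are aligned by projecting the extracted
#' path's start onto the analytic axis.
#'
#' @param n_phantoms number of phantoms.
#' @param seed base RNG seed.
#' @param spacing rasterization spacing (mm).
#' @param step straightening step (mm).
#' @return object of class `caliber_validation`: `report` tibble
#'   (`phantom`, `min_area_s`, `max_area_s`, ground-truth intervals,
#'   `stenosis_hit`, `dilation_hit`, `correct`) and `accuracy` (percent of
#'   phantoms with both features localized).
#' @export
validate_caliber_localization <- function(n_phantoms = 20, seed = 1L,
                                          spacing = 0.5, step = 0.5) {
  rows <- list()
  for (i in seq_len(n_phantoms)) {
    ph_seed <- (seed * 977L + i) %% .Machine$integer.max
    ph <- make_stenosis_phantom(seed = ph_seed, spacing = spacing)
    cl <- extract_centerline(ph$mask, ph$seeds$start, ph$seeds$end, step = 1)
    stack <- propagate_planes(cl, half_size_mm = 2.2 * 3 * 1.5 / 2,
                              in_plane_spacing = spacing, step = step)
    sv <- resample_on_planes(ph$mask, stack, sentinel = 0)
    prof <- assess_caliber_profile(sv, lumen_threshold = 0.5)
    # arc offset: where does the extracted path start on the analytic axis?
    d0 <- sqrt(rowSums(sweep(ph$reference, 2L, cl$points[1, ], `-`)^2))
    s0 <- ph$reference_s[which.min(d0)]
    min_s <- prof$min_area_s + s0
    max_s <- prof$max_area_s + s0
    st_hit <- min_s >= ph$stenosis[1] && min_s <= ph$stenosis[2]
    di_hit <- max_s >= ph$dilation[1] && max_s <= ph$dilation[2]
    rows[[i]] <- tibble::tibble(
      phantom = i, min_area_s = min_s, max_area_s = max_s,
      stenosis_lo = ph$stenosis[1], stenosis_hi = ph$stenosis[2],
      dilation_lo = ph$dilation[1], dilation_hi = ph$dilation[2],
      stenosis_hit = st_hit, dilation_hit = di_hit,
      correct = st_hit && di_hit)
  }
  report <- dplyr::bind_rows(rows)
  structure(list(report = report,
                 accuracy = 100 * mean(report$correct),
                 n_phantoms = n_phantoms),
            class = "caliber_validation")
}

#' @export
print.caliber_validation <- function(x, ...) {
  cat(sprintf("<caliber_validation> %d phantoms, %.1f%% with both features localized\n",
              x$n_phantoms, x$accuracy))
  invisible(x)
}
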