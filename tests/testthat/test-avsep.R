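test_that("compute_ttp closed forms: midpoint, exact zero, no crossing", {
  # symmetric crossing: v' = 1 at t = 2, v' = -1 at t = 3 -> 2.5 s
  expect_equal(compute_ttp(c(2, 1, -1, -2), times = 1:4), 2.5)
  # exact zero at the crossing sample -> t_(I+1) itself
  expect_equal(compute_ttp(c(2, 1, 0, -2), times = 1:4), 3)
  # flat crossing (a = 0 limit) also lands on t_(I+1)
  expect_equal(compute_ttp(c(1, 0, 0, -1), times = 1:4), 2)
  # never turns non-positive after its peak -> NaN, not an error
  expect_true(is.nan(compute_ttp(c(1, 2, 3, 4), times = 1:4)))
  expect_true(is.nan(compute_ttp(rep(0, 4), times = 1:4)))
  expect_true(is.nan(compute_ttp(c(-1, -2, -3, -1), times = 1:4)))
})

test_that("compute_ttp is amplitude-invariant and shifts with time", {
  vp <- c(0.5, 2, 1.2, -0.7, -2)
  tt <- c(0, 2, 4, 6, 8)
  t0 <- compute_ttp(vp, tt)
  expect_equal(compute_ttp(7.3 * vp, tt), t0)
  expect_equal(compute_ttp(vp, tt + 11), t0 + 11)
})

test_that("TTP of a filtered gamma-variate lands within a frame of the peak", {
  # bolus peaking at 5 + 3 * 1.5 = 9.5 s, sampled at 0.5 s
  tac_model <- tac_gamma_variate(t0 = 5, alpha = 3, beta = 1.5,
                                 amplitude = 300, baseline = 40)
  tt <- seq(0, 20, by = 0.5)
  vp <- filter_tac(tac_eval(tac_model, tt), dog_filter(3, 5))
  t_est <- compute_ttp(vp, tt)
  t_true <- oracle_peak_time(tac_model)
  expect_equal(t_true, 9.5, tolerance = 1e-2)
  expect_lt(abs(t_est - t_true), 0.5)
})

test_that("compute_ttp_map equals the per-voxel scalar oracle", {
  ras <- small_scene()
  vm <- ras$labels %in% 1:2
  f <- dog_filter(3, 5)
  tm <- compute_ttp_map(ras$series, vm, f)
  idx <- which(vm)
  probe <- idx[round(seq(1, length(idx), length.out = 25))]
  for (v in probe) {
    ijk <- arrayInd(v, dim(ras$labels))
    tac <- ras$series$values[ijk[1], ijk[2], ijk[3], ]
    expect_equal(tm$ttp[v], compute_ttp(filter_tac(tac, f), ras$series$times))
  }
  expect_error(compute_ttp_map(ras$series, vm & FALSE, f), "empty")
})

test_that("noise-free phantom: artery TTPs identical, all earlier than veins", {
  ras <- small_scene()
  vm <- ras$labels %in% 1:2
  tm <- compute_ttp_map(ras$series, vm)
  ta <- tm$ttp[ras$labels == 1]
  tv <- tm$ttp[ras$labels == 2]
  expect_lt(diff(range(ta)), 1e-9)
  expect_lt(max(ta), min(tv))
})

test_that("valley threshold splits two delta-like modes with the tie rule", {
  vals <- c(rep(10, 500), rep(20, 300))
  av <- find_valley_threshold(vals, n_bins = 20)
  expect_gt(av$v_ttp, 10)
  expect_lt(av$v_ttp, 20)
  expect_lt(av$peak_bins[1], av$valley_bin)
  expect_gt(av$peak_bins[2], av$valley_bin)
  # flat zero valley: the tie breaks toward the lowest-TTP empty bin
  counts <- av$histogram$count
  between <- (av$peak_bins[1] + 1):(av$peak_bins[2] - 1)
  first_min <- between[which.min(counts[between])]
  expect_equal(av$valley_bin, first_min)
  expect_equal(counts[av$valley_bin],
               min(counts[between]))
})

test_that("valley of a two-Gaussian mixture falls in the inter-mode density gap", {
  set.seed(4)
  vals <- c(rnorm(4000, 10, 1), rnorm(4000, 20, 1))
  av <- find_valley_threshold(vals, n_bins = 60)
  # fine-grid oracle: analytic mixture density minimum (15 by symmetry) and
  # the near-zero-density gap around it
  grid <- seq(8, 22, by = 1e-3)
  dens <- dnorm(grid, 10, 1) + dnorm(grid, 20, 1)
  t_min <- grid[which.min(dens)]
  expect_equal(t_min, 15, tolerance = 1e-2)
  gap <- range(grid[dens < 0.05 * max(dens)])
  # the detected peaks bracket the modes; the valley (lowest-TTP tied empty
  # bin, per the tie rule) lies inside the low-density gap around t_min
  expect_lt(abs(av$histogram$mid[av$peak_bins[1]] - 10), 0.5)
  expect_lt(abs(av$histogram$mid[av$peak_bins[2]] - 20), 0.5)
  expect_gte(av$v_ttp, gap[1])
  expect_lte(av$v_ttp, gap[2])
  expect_lte(av$v_ttp, t_min)               # tie rule favours the lower TTP
})

test_that("degenerate and unimodal histograms refuse with advice", {
  expect_error(find_valley_threshold(rep(10, 50)), "manually")
  # deterministic strictly unimodal histogram
  vals <- rep(seq(9, 11, length.out = 11),
              times = c(1, 3, 8, 15, 25, 30, 25, 15, 8, 3, 1))
  expect_error(find_valley_threshold(vals, n_bins = 11), "manually")
})

test_that("artery/vein separation partitions the vessel mask", {
  ras <- small_scene()
  vm <- ras$labels %in% 1:2
  tm <- compute_ttp_map(ras$series, vm)
  av <- find_valley_threshold(tm)
  sep <- separate_arteries_veins(tm, vm, av)
  expect_false(any(sep$artery & sep$vein))
  expect_identical(as.vector(sep$artery | sep$vein), as.vector(vm))
  # 100% label accuracy on the noise-free phantom
  expect_identical(as.vector(sep$artery), as.vector(ras$labels == 1))
  expect_identical(as.vector(sep$vein), as.vector(ras$labels == 2))
  # a threshold below every TTP empties the artery mask
  sep0 <- separate_arteries_veins(tm, vm, 0)
  expect_false(any(sep0$artery))
  expect_identical(as.vector(sep0$vein), as.vector(vm))
})

test_that("undefined-TTP voxels are assigned to the veins", {
  # artery-like voxel plus a voxel still rising at scan end
  arr <- array(40, c(2, 1, 1, 8))
  tt <- seq(0, 14, by = 2)
  arr[1, 1, 1, ] <- tac_eval(tac_gamma_variate(2, 2, 1.5, 300), tt)
  arr[2, 1, 1, ] <- 40 + seq(0, 140, by = 20)     # monotone: no peak
  s <- ctp_series(arr, times = tt)
  vm <- array(TRUE, c(2, 1, 1))
  tm <- compute_ttp_map(s, vm)
  expect_true(is.nan(tm$ttp[2, 1, 1]))
  sep <- separate_arteries_veins(tm, vm, 10)
  expect_true(sep$vein[2, 1, 1])
  expect_true(sep$artery[1, 1, 1])
})

test_that("shifting all frame times shifts every TTP and the valley alike", {
  ras <- small_scene()
  vm <- ras$labels %in% 1:2
  tm1 <- compute_ttp_map(ras$series, vm)
  shifted <- ctp_series(ras$series$values, times = ras$series$times + 7,
                        spacing = ras$series$spacing)
  tm2 <- compute_ttp_map(shifted, vm)
  d <- tm2$ttp[vm] - tm1$ttp[vm]
  expect_true(all(abs(d - 7) < 1e-9, na.rm = TRUE))
  v1 <- find_valley_threshold(tm1)$v_ttp
  v2 <- find_valley_threshold(tm2)$v_ttp
  expect_equal(v2 - v1, 7, tolerance = 1e-9)
})
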