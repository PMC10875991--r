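test_that("gamma-variate TAC has its closed-form peak and a flat pre-bolus", {
  tac <- tac_gamma_variate(t0 = 4, alpha = 3, beta = 2, amplitude = 300,
                           baseline = 40)
  expect_equal(tac_peak_time(tac), 10)
  expect_equal(tac_eval(tac, c(0, 2, 4)), rep(40, 3))
  expect_equal(tac_eval(tac, 10), 340)
  # dense-sampling argmax agrees with the analytic peak
  expect_equal(oracle_peak_time(tac), 10, tolerance = 1e-2)
  expect_lt(tac_eval(tac, 9.5), tac_eval(tac, 10))
  expect_lt(tac_eval(tac, 10.5), tac_eval(tac, 10))
})

test_that("noise-free rasterization reproduces each label's TAC exactly", {
  ras <- small_scene()
  sc <- phantom_scene(shape = c(48, 48, 40), spacing = 0.5, noise_sigma = 0)
  tt <- ras$series$times
  for (lab in 1:3) {
    idx <- which(ras$labels == lab)
    expect_gt(length(idx), 0)
    vox <- idx[c(1, length(idx) %/% 2, length(idx))]
    model <- switch(lab, sc$artery_tac, sc$vein_tac, sc$soft_tissue_tac)
    for (v in vox) {
      got <- vapply(seq_along(tt), function(f) {
        ijk <- arrayInd(v, dim(ras$labels))
        ras$series$values[ijk[1], ijk[2], ijk[3], f]
      }, numeric(1))
      expect_equal(got, tac_eval(model, tt), tolerance = 1e-12)
    }
  }
  # skull shell constant at its nominal HU, background at 0
  expect_true(all(ras$series$values[, , , 1][ras$labels == 4] == 1000))
  expect_true(all(ras$series$values[, , , 10][ras$labels == 0] == 0))
})

test_that("labels are mutually exclusive and artery peaks before vein", {
  ras <- small_scene()
  sc <- phantom_scene()
  expect_true(all(ras$labels %in% 0:4))
  expect_gt(tac_peak_time(sc$vein_tac), tac_peak_time(sc$artery_tac))
  expect_error(phantom_scene(artery_tac = tac_gamma_variate(8, 4, 3),
                             vein_tac = tac_gamma_variate(4, 3, 2)),
               "peak strictly later")
})

test_that("noisy rasterization is seed-reproducible, noise-free is seed-free", {
  sc_a <- phantom_scene(shape = c(40, 40, 32), noise_sigma = 4, seed = 11)
  sc_b <- phantom_scene(shape = c(40, 40, 32), noise_sigma = 4, seed = 11)
  expect_identical(rasterize_scene(sc_a)$series$values,
                   rasterize_scene(sc_b)$series$values)
  sc_c <- phantom_scene(shape = c(40, 40, 32), noise_sigma = 0, seed = 1)
  sc_d <- phantom_scene(shape = c(40, 40, 32), noise_sigma = 0, seed = 99)
  expect_identical(rasterize_scene(sc_c)$series$values,
                   rasterize_scene(sc_d)$series$values)
})

test_that("rasterized tube cross-section area matches the analytic disc", {
  tb <- straight_tube(radius = 3, length_mm = 10, spacing = 0.5)
  # voxel-counting oracle vs pi r^2, interior slices
  areas <- oracle_slice_areas(tb$mask, tb$spacing)
  mid <- areas[5:(length(areas) - 5)]
  expect_true(all(abs(mid - pi * 9) / (pi * 9) < 0.1))
  # and the generator's own rasterizer on a line curve
  spec <- tube_spec(curve_line(c(8, 8, 4), c(0, 0, 1), 8), radius = 3,
                    label = "none")
  shape <- c(33, 33, 33)
  ras <- ctpangio:::rasterize_tube_spec(spec, shape, rep(0.5, 3), c(0, 0, 0))
  a2 <- oracle_slice_areas(ras$main, 0.5)
  zw <- (seq_len(shape[3]) - 1) * 0.5
  interior <- a2[zw >= 4.5 & zw <= 11.5]   # between the hemispherical caps
  expect_true(all(abs(interior - pi * 9) / (pi * 9) < 0.1))
})

test_that("a tube leaving the grid names itself in the error", {
  spec <- tube_spec(curve_line(c(8, 8, 0), c(0, 0, 1), 50), radius = 3,
                    label = "none")
  expect_error(
    ctpangio:::rasterize_tube_spec(spec, c(33, 33, 20), rep(0.5, 3), c(0, 0, 0),
                                   name = "runaway"),
    "runaway")
})

test_that("deviation phantoms carry the requested branch count", {
  for (nb in c(0, 3, 6)) {
    ph <- make_deviation_phantom(nb, seed = 40 + nb)
    cc <- ctpangio:::label_components(ph$branch_mask)
    expect_equal(length(cc$sizes), nb)
    # reference axis lies strictly inside the rasterized tube
    vox <- ctpangio:::world_to_voxel(ph$reference, ph$spacing, c(0, 0, 0))
    inside <- ph$mask[round(vox)]
    expect_true(all(inside))
  }
})

test_that("stenosis phantom's narrowest/widest sections sit in the true intervals", {
  ph <- make_stenosis_phantom(seed = 5)
  # voxel-counting oracle: assign every tube voxel to its nearest axis sample
  idx <- which(ph$mask, arr.ind = TRUE)
  w <- ctpangio:::voxel_to_world(idx, ph$spacing, c(0, 0, 0))
  near_s <- vapply(seq_len(nrow(w)), function(i) {
    ph$reference_s[which.min(colSums((t(ph$reference) - w[i, ])^2))]
  }, numeric(1))
  bins <- seq(0, ph$length, by = 2)
  counts <- tabulate(findInterval(near_s, bins, rightmost.closed = TRUE),
                     length(bins) - 1)
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  interior <- mids > 3 & mids < ph$length - 3
  min_s <- mids[interior][which.min(counts[interior])]
  max_s <- mids[interior][which.max(counts[interior])]
  expect_gte(min_s, ph$stenosis[1])
  expect_lte(min_s, ph$stenosis[2])
  expect_gte(max_s, ph$dilation[1])
  expect_lte(max_s, ph$dilation[2])
})

test_that("radius profile is constant without features and overlap errors", {
  crv <- curve_line(c(0, 0, 0), c(0, 0, 1), 60)
  plain <- tube_spec(crv, radius = 3, label = "none")
  expect_equal(plain$radius_at(seq(0, 60, by = 1)), rep(3, 61))
  expect_error(tube_spec(crv, radius = 3, stenosis = c(20, 30, 0.5),
                         dilation = c(25, 35, 1.5), label = "none"),
               "overlap")
  expect_error(tube_spec(crv, radius = 3, stenosis = c(20, 30, 1.2),
                         label = "none"), "radius_factor")
  expect_error(tube_spec(crv, radius = 3, dilation = c(20, 30, 0.8),
                         label = "none"), "radius_factor")
})

test_that("phantoms round-trip to disk with their JSON ground truth", {
  dir <- withr::local_tempdir()
  ph <- make_deviation_phantom(3, seed = 2)
  paths <- write_phantom(ph, dir, name = "dev")
  expect_true(all(file.exists(paths)))
  gt <- jsonlite::read_json(file.path(dir, "dev_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$n_branches, 3)
  m <- read_mask(file.path(dir, "dev_mask.nii.gz"))
  expect_equal(sum(m), sum(ph$mask))
})
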