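test_that("Rodrigues rotation closed forms", {
  v <- c(1, 0, 0)
  expect_equal(rotate_vector(v, c(0, 0, 1), 0), v)
  expect_equal(rotate_vector(v, c(0, 0, 1), pi / 2), c(0, 1, 0),
               tolerance = 1e-12)
  # vectors parallel to the axis are invariant for any angle
  expect_equal(rotate_vector(c(0, 0, 2.5), c(0, 0, 1), 1.234), c(0, 0, 2.5),
               tolerance = 1e-12)
  expect_error(rotate_vector(v, c(0, 0, 2), 1), "unit")
})

test_that("rotation preserves norms and angles to 1e-9 on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    u <- ctpangio:::normalize3(rnorm(3))
    th <- runif(1, -pi, pi)
    a <- rnorm(3); b <- rnorm(3)
    ra <- rotate_vector(a, u, th)
    rb <- rotate_vector(b, u, th)
    expect_lt(abs(sqrt(sum(ra^2)) - sqrt(sum(a^2))), 1e-9)
    expect_lt(abs(sum(ra * rb) - sum(a * b)), 1e-9)
    # composition about one axis adds angles
    th2 <- runif(1, -pi, pi)
    expect_lt(max(abs(rotate_vector(rotate_vector(a, u, th), u, th2) -
                        rotate_vector(a, u, th + th2))), 1e-9)
  }
})

test_that("initial plane is a centred uniform grid perpendicular to z", {
  p <- initial_plane(1, spacing = 1)
  expect_equal(nrow(p), 9L)
  expect_equal(colMeans(p), c(x = 0, y = 0, z = 0))
  expect_true(all(p[, 3] == 0))
  # corner-to-centre distance m * spacing * sqrt(2)
  p2 <- initial_plane(4, spacing = 0.5)
  corners <- sqrt(rowSums(p2^2))
  expect_equal(max(corners), 4 * 0.5 * sqrt(2), tolerance = 1e-12)
})

test_that("straight centerline propagates by pure translation", {
  pts <- cbind(0, 0, seq(0, 10, by = 1))
  cl <- centerline(pts)
  stack <- propagate_planes(cl, half_size_mm = 2, in_plane_spacing = 1,
                            step = 1)
  expect_true(all(stack$rotations$theta == 0))
  p1 <- stack$planes[, , 1]
  for (k in 2:dim(stack$planes)[3]) {
    shift <- sweep(stack$planes[, , k], 2, stack$centers[k, ] - stack$centers[1, ])
    expect_equal(shift, p1, tolerance = 1e-9)
  }
})

test_that("a 90-degree arc turns the final plane normal perpendicular", {
  R <- 20
  ang <- seq(0, pi / 2, length.out = 91)
  pts <- cbind(R * sin(ang), 0, R - R * cos(ang))   # starts along +z... tangent
  cl <- centerline(pts)
  stack <- propagate_planes(cl, half_size_mm = 2, in_plane_spacing = 1,
                            step = 0.5)
  n <- dim(stack$planes)[3]
  # oracle: accumulating the per-step analytic rotations turns the tangent
  # by the full arc angle, so first and last normals are orthogonal
  expect_lt(abs(sum(stack$normals[1, ] * stack$normals[n, ])), 0.05)
  # plane normals equal the centerline tangents
  for (k in c(1, round(n / 2), n)) {
    e1 <- stack$planes[2, , k] - stack$planes[1, , k]
    expect_lt(abs(sum(e1 * stack$normals[k, ])), 1e-6)
  }
})

test_that("every propagated plane is an isometric copy of the template", {
  ph <- make_stenosis_phantom(seed = 3)
  cl <- centerline(ph$reference[seq(1, nrow(ph$reference), by = 20), ])
  stack <- propagate_planes(cl, half_size_mm = 3, in_plane_spacing = 1,
                            step = 1)
  p0 <- stack$planes[, , 1]
  idx <- cbind(c(1, 1, 5, 12), c(9, 25, 30, 40))
  d0 <- sqrt(rowSums((p0[idx[, 1], ] - p0[idx[, 2], ])^2))
  for (k in seq(2, dim(stack$planes)[3], by = 7)) {
    pk <- stack$planes[, , k]
    dk <- sqrt(rowSums((pk[idx[, 1], ] - pk[idx[, 2], ])^2))
    expect_equal(dk, d0, tolerance = 1e-9)
  }
  expect_true(all(abs(sqrt(stack$rotations$ux^2 + stack$rotations$uy^2 +
                             stack$rotations$uz^2)[stack$rotations$theta > 0] - 1)
                  < 1e-9))
})

test_that("anti-parallel consecutive tangents are rejected", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 0.5))
  expect_error(propagate_planes(centerline(pts), half_size_mm = 1,
                                in_plane_spacing = 1, step = 5),
               "anti-parallel")
})

test_that("straightening a straight tube along its own axis is the identity", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  cl <- centerline(tb$axis)
  m <- round(5 / 0.5)
  stack <- propagate_planes(cl, half_size_mm = 5, in_plane_spacing = 0.5,
                            step = 0.5)
  sv <- resample_on_planes(tb$mask, stack, sentinel = 0)
  # direct crop oracle: sample grid coincides with voxel centres, so values
  # must match the source mask exactly
  nxy <- dim(tb$mask)[1]
  ctr_idx <- (nxy + 1) / 2
  sel <- (ctr_idx - m):(ctr_idx + m)
  for (k in c(3, 21, 39)) {
    src <- tb$mask[sel, sel, k] * 1
    expect_equal(max(abs(sv$values[, , k] - src)), 0)
  }
})

test_that("uniform volumes straighten to the uniform value; all-outside errors", {
  vol <- vol3d(array(7, c(10, 10, 10)), spacing = rep(1, 3))
  cl <- centerline(cbind(4.5, 4.5, 1:8))
  stack <- propagate_planes(cl, half_size_mm = 2, in_plane_spacing = 0.5,
                            step = 1)
  sv <- resample_on_planes(vol, stack, sentinel = NA)
  expect_true(all(sv$values == 7))
  far <- centerline(cbind(500, 500, 501:508))
  stack_far <- propagate_planes(far, half_size_mm = 2, in_plane_spacing = 0.5,
                                step = 1)
  expect_error(resample_on_planes(vol, stack_far), "outside")
})

test_that("curved constant-radius tube keeps its cross-section after straightening", {
  ph <- make_deviation_phantom(0, seed = 31)
  cl <- extract_centerline(ph$mask, ph$seeds$start, ph$seeds$end, step = 1)
  stack <- propagate_planes(cl, half_size_mm = 5, in_plane_spacing = 0.5,
                            step = 0.5)
  sv <- resample_on_planes(ph$mask, stack, sentinel = 0)
  prof <- assess_caliber_profile(sv, lumen_threshold = 0.5)
  interior <- prof$profile$area[5:(nrow(prof$profile) - 5)]
  expect_true(all(abs(interior - pi * 9) / (pi * 9) < 0.15))
  expect_length(prof$stenosis_intervals, 0)
  expect_length(prof$dilation_intervals, 0)
})

test_that("stenosis dips to a quarter of the baseline area and is localized", {
  ph <- make_stenosis_phantom(seed = 8, stenosis_factor = 0.5,
                              dilation_factor = 1.5)
  cl <- extract_centerline(ph$mask, ph$seeds$start, ph$seeds$end, step = 1)
  stack <- propagate_planes(cl, half_size_mm = 5, in_plane_spacing = 0.5,
                            step = 0.5)
  sv <- resample_on_planes(ph$mask, stack, sentinel = 0)
  prof <- assess_caliber_profile(sv)
  base <- prof$median_area
  expect_equal(min(prof$profile$area) / base, 0.25, tolerance = 0.2)
  expect_equal(max(prof$profile$area) / base, 2.25, tolerance = 0.2)
  # flagged stenotic interval overlaps the ground truth
  d0 <- sqrt(rowSums(sweep(ph$reference, 2, cl$points[1, ], `-`)^2))
  s0 <- ph$reference_s[which.min(d0)]
  hit <- any(vapply(prof$stenosis_intervals, function(iv) {
    iv[1] + s0 <= ph$stenosis[2] && iv[2] + s0 >= ph$stenosis[1]
  }, logical(1)))
  expect_true(hit)
  expect_error(assess_caliber_profile(
    structure(list(values = array(0, c(3, 3, 3)), spacing = c(1, 1, 1),
                   arc_length = 0:2, sentinel = 0),
              class = "straightened_volume")), "no lumen")
})
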