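test_that("extract_wall yields a one-voxel shell with empty interior", {
  ball <- ball_mask(radius = 5, spacing = 1)
  wall <- extract_wall(ball)
  interior <- ball & !wall
  expect_true(any(interior))
  expect_identical(as.vector(interior), as.vector(ctpangio:::erode6(ball)))
  # the shell itself erodes away completely
  expect_false(any(ctpangio:::erode6(wall)))
  # single voxel is its own wall
  single <- vol3d(array(FALSE, c(3, 3, 3)))
  single[2, 2, 2] <- TRUE
  expect_identical(as.vector(extract_wall(single)), as.vector(single))
  expect_error(extract_wall(single & FALSE), "empty")
  # several components: largest wins, with a warning
  two <- vol3d(array(FALSE, c(9, 3, 3)))
  two[1:5, 1:2, 1:2] <- TRUE
  two[8:9, 1, 1] <- TRUE
  expect_warning(w <- extract_wall(two), "largest")
  expect_false(any(w[8:9, , ]))
})

test_that("straight-tube wall voxel count tracks the analytic lateral surface", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  wall <- extract_wall(tb$mask)
  interior_slices <- 3:(dim(wall)[3] - 3)
  n_wall <- sum(wall[, , interior_slices])
  # analytic-surface oracle: lateral area / voxel cross-section, with the
  # staircase factor for a 1-voxel shell in [1, ~1.6]
  expected <- 2 * pi * tb$radius * (length(interior_slices) * tb$spacing) /
    tb$spacing^2
  expect_gt(n_wall, 0.8 * expected)
  expect_lt(n_wall, 1.8 * expected)
})

test_that("mesh of a ball matches the analytic sphere area and is closed", {
  ball <- ball_mask(radius = 10, spacing = 0.5)
  mesh <- build_mesh(ball)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_equal(mesh_euler(mesh), 2)        # closed genus-0 surface
})

test_that("mesh of a tube is genus 0 and hugs the voxel wall", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  mesh <- build_mesh(tb$mask)
  expect_equal(mesh_euler(mesh), 2)
  # every sampled vertex lies within one voxel of a wall voxel centre
  wall <- extract_wall(tb$mask)
  wpts <- ctpangio:::voxel_to_world(which(wall, arr.ind = TRUE),
                                    rep(0.5, 3), c(0, 0, 0))
  probe <- mesh$vertices[round(seq(1, nrow(mesh$vertices), length.out = 60)), ]
  for (i in seq_len(nrow(probe))) {
    d <- min(sqrt(rowSums(sweep(wpts, 2, probe[i, ], `-`)^2)))
    expect_lt(d, sqrt(3) * 0.5)
  }
  expect_error(build_mesh(vol3d(array(FALSE, c(4, 4, 4)))), "empty")
})

test_that("contour centroids: area-weighted equals vertex mean on circles", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  mesh <- build_mesh(tb$mask)
  for (z in c(6, 10, 14)) {
    cons <- ctpangio:::slice_mesh(mesh, c(tb$center_mm, tb$center_mm, z),
                                  c(0, 0, 1))
    expect_equal(length(cons), 1L)
    cc <- ctpangio:::contour_centroid(cons[[1]], c(0, 0, 1))
    vmean <- colMeans(cons[[1]])
    expect_lt(sqrt(sum((cc$centroid - vmean)^2)), 0.1)
    expect_equal(cc$area, pi * 9, tolerance = 0.05)
    # both estimators sit on the tube axis
    expect_lt(sqrt(sum((cc$centroid[1:2] - tb$center_mm)^2)), 0.1)
  }
})

test_that("straight tube: centroids collinear, Dijkstra path on the axis", {
  tb <- straight_tube(radius = 3, length_mm = 30, spacing = 0.5)
  start <- tb$axis[1, ]
  end <- tb$axis[nrow(tb$axis), ]
  mesh <- build_mesh(tb$mask)
  g <- cross_section_centroids(mesh, start, end, step = 1)
  # all centroids within half a voxel of the axis
  lat <- sqrt((g$nodes$x - tb$center_mm)^2 + (g$nodes$y - tb$center_mm)^2)
  expect_lt(max(lat), 0.5 * tb$spacing)
  cl <- shortest_path_centerline(g)
  dev <- centerline_deviation(cl, tb$axis)
  expect_lt(dev$max, 0.5 * tb$spacing)
  # tangents of a straight path are all the same unit vector
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, nrow(cl$tangents)),
               tolerance = 1e-9)
  # extracted nodes carry sub-voxel numerical wobble; tangents agree to ~mrad
  expect_lt(max(abs(sweep(cl$tangents, 2, cl$tangents[1, ]))), 5e-3)
  # metric lower bound and monotone arc length
  expect_gte(max(cl$arc_length) + 1e-9,
             sqrt(sum((cl$points[nrow(cl$points), ] - cl$points[1, ])^2)))
  expect_true(all(diff(cl$arc_length) > 0))
})

test_that("junction slices yield several contours; the path avoids branches", {
  ph <- make_deviation_phantom(3, seed = 21)
  mesh <- build_mesh(ph$mask)
  g <- cross_section_centroids(mesh, ph$seeds$start, ph$seeds$end, step = 1)
  per_slice <- table(g$nodes$slice)
  expect_gt(max(per_slice), 1)            # branch contours become extra nodes
  cl <- shortest_path_centerline(g)
  nd <- centerline_deviation(as.matrix(g$nodes[, c("x", "y", "z")]),
                             ph$reference)$distances
  expect_gt(max(nd), 2)                   # branch nodes sit far off-axis
  dev <- centerline_deviation(cl, ph$reference)
  expect_lt(dev$max, 1)                   # but the path skirts them
  # every path point stays inside the tube mask
  vox <- round(ctpangio:::world_to_voxel(cl$points, ph$spacing, c(0, 0, 0)))
  expect_true(all(ph$mask[vox]))
})

test_that("seed handling: outside bounding volume and unreachable snaps fail", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  mesh <- build_mesh(tb$mask)
  expect_error(cross_section_centroids(mesh, c(200, 200, 200), tb$axis[1, ]),
               "bounding volume")
  # a seed inside the box but > 5 mm from any centroid fails to snap
  far <- tb$axis[1, ] + c(6.5, 6.5, 0)
  expect_error(cross_section_centroids(mesh, tb$axis[1, ] + c(0, 0, 1), far),
               "5 mm")
})

test_that("disconnected centroid graphs report their components", {
  nodes <- tibble::tibble(id = 1:4, x = c(0, 1, 10, 11), y = 0, z = 0,
                          slice = c(1L, 2L, 7L, 8L), area = 1)
  edges <- tibble::tibble(from = c(1L, 3L), to = c(2L, 4L), weight = 1)
  g <- structure(list(nodes = nodes, edges = edges, start_node = 1L,
                      end_node = 4L, step = 1), class = "centroid_graph")
  expect_error(shortest_path_centerline(g), "components")
})

test_that("deviation metric: identity, rigid offset, resampling refinement", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  cl <- centerline(tb$axis)
  same <- centerline_deviation(cl, tb$axis)
  expect_equal(c(same$mean, same$sd, same$max), c(0, 0, 0))
  shifted <- sweep(tb$axis, 2, c(0.2, 0, 0), `+`)
  off <- centerline_deviation(centerline(shifted), tb$axis)
  expect_equal(off$mean, 0.2, tolerance = 1e-9)
  expect_equal(off$max, 0.2, tolerance = 1e-9)
  # point-to-segment distances are invariant to reference refinement
  coarse <- tb$axis[seq(1, nrow(tb$axis), by = 8), ]
  fine <- tb$axis
  d1 <- centerline_deviation(centerline(shifted), coarse)
  d2 <- centerline_deviation(centerline(shifted), fine)
  expect_equal(d1$mean, d2$mean, tolerance = 1e-6)
})

test_that("inscribed radius along a straight-tube centerline equals the lumen radius", {
  tb <- straight_tube(radius = 3, length_mm = 20, spacing = 0.5)
  cl <- centerline(tb$axis[10:30, ])
  wall <- extract_wall(tb$mask)
  r <- inscribed_radius(cl, wall)
  expect_true(all(abs(r - tb$radius) < 0.5))
})

test_that("centerline tangents follow the difference scheme", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(3, 3, 0))
  cl <- centerline(pts)
  expect_equal(cl$tangents[1, ], c(1, 0, 0))
  expect_equal(cl$tangents[2, ],
               (pts[3, ] - pts[1, ]) / sqrt(sum((pts[3, ] - pts[1, ])^2)))
  expect_equal(cl$tangents[4, ],
               (pts[4, ] - pts[3, ]) / sqrt(sum((pts[4, ] - pts[3, ])^2)))
  expect_equal(unname(sqrt(rowSums(cl$tangents^2))), rep(1, 4))
})
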