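# Shared fixtures (built in code, memoized across test files) and
# independent oracles used by the derived-value tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small noise-free CTP scene with skull, artery (peak 10 s), vein (peak 20 s)
small_scene <- function() {
  fixture("small_scene", rasterize_scene(
    phantom_scene(shape = c(48, 48, 40), spacing = 0.5, noise_sigma = 0)))
}

small_scene_noisy <- function(sigma = 5) {
  fixture(paste0("small_scene_noisy", sigma), rasterize_scene(
    phantom_scene(shape = c(48, 48, 40), spacing = 0.5, noise_sigma = sigma,
                  seed = 7)))
}

# straight tube along z whose axis passes exactly through voxel centres
straight_tube <- function(radius = 3, length_mm = 30, spacing = 0.5,
                          margin = 4) {
  key <- paste("tube", radius, length_mm, spacing, margin)
  fixture(key, {
    half <- radius + margin
    nxy <- 2L * round(half / spacing) + 1L
    c_mm <- (nxy - 1L) / 2 * spacing
    nz <- round(length_mm / spacing) + 1L
    xs <- (seq_len(nxy) - 1) * spacing - c_mm
    r2 <- outer(xs^2, xs^2, `+`)
    sl <- r2 <= radius^2
    mask <- array(FALSE, c(nxy, nxy, nz))
    for (k in seq_len(nz)) mask[, , k] <- sl
    axis <- cbind(c_mm, c_mm, (seq_len(nz) - 1) * spacing)
    list(mask = vol3d(mask, spacing = rep(spacing, 3)),
         axis = axis, radius = radius, spacing = spacing,
         center_mm = c_mm, length_mm = length_mm)
  })
}

# solid ball mask, radius in mm
ball_mask <- function(radius = 10, spacing = 0.5, margin = 3) {
  key <- paste("ball", radius, spacing, margin)
  fixture(key, {
    n <- 2L * round((radius + margin) / spacing) + 1L
    c_mm <- (n - 1L) / 2 * spacing
    g <- (seq_len(n) - 1) * spacing - c_mm
    d2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
    vol3d(d2 <= radius^2, spacing = rep(spacing, 3))
  })
}

# oracle: direct convolution with edge replication (independent of the
# package's vectorized implementation)
oracle_conv <- function(v, taps) {
  h <- (length(taps) - 1L) / 2L
  T_ <- length(v)
  out <- numeric(T_)
  for (i in seq_len(T_)) {
    s <- 0
    for (j in seq_along(taps)) {
      off <- j - h - 1L
      idx <- min(max(i - off, 1L), T_)
      s <- s + taps[j] * v[idx]
    }
    out[i] <- s
  }
  out
}

# oracle: FG by brute-force per-voxel summation
oracle_fg <- function(tac, taps) sum(abs(oracle_conv(tac, taps)))

# oracle: densely sampled argmax of an analytic TAC
oracle_peak_time <- function(tac_model, t_max = 40) {
  tt <- seq(0, t_max, by = 1e-3)
  tt[which.max(tac_eval(tac_model, tt))]
}

# oracle: per-slice cross-section voxel count of a mask along z
oracle_slice_areas <- function(mask, spacing) {
  vapply(seq_len(dim(mask)[3]), function(k) sum(mask[, , k]) * spacing^2,
         numeric(1))
}
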