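# Vessel trees, pulsatility profiles and scatterer advection.

test_that("vessel trees are deterministic per seed and empty when rootless", {
  t0 <- make_vessel_tree(seed = 1, n_roots = 0, branching_depth = 0,
                         parallel_pair = FALSE)
  expect_length(t0$segments, 0)
  expect_equal(vessel_tree_length(t0), 0)

  t1 <- make_vessel_tree(seed = 7, n_roots = 2, branching_depth = 2)
  t2 <- make_vessel_tree(seed = 7, n_roots = 2, branching_depth = 2)
  expect_identical(t1$segments, t2$segments)
  t3 <- make_vessel_tree(seed = 8, n_roots = 2, branching_depth = 2)
  expect_false(identical(t1$segments, t3$segments))
})

test_that("every centerline point lies inside the field of view", {
  tr <- make_vessel_tree(seed = 1, n_roots = 2, branching_depth = 3)
  fov <- tr$field_of_view
  for (seg in tr$segments) {
    expect_true(all(seg$points[, 1] >= 0 & seg$points[, 1] <= fov[1]))
    expect_true(all(seg$points[, 2] >= 0 & seg$points[, 2] <= fov[2]))
    expect_gt(seg$radius, 0)
  }
})

test_that("child segments never exceed their parent radius", {
  tr <- make_vessel_tree(seed = 5, n_roots = 2, branching_depth = 3)
  for (i in seq_along(tr$segments)) {
    p <- tr$segments[[i]]$parent
    if (!is.na(p)) {
      expect_lte(tr$segments[[i]]$radius, tr$segments[[p]]$radius)
    }
  }
})

test_that("trees with branching depth >= 2 include the sub-diffraction pair", {
  tr <- make_vessel_tree(seed = 2, n_roots = 1, branching_depth = 2)
  ln <- pair_cross_line(tr)
  expect_equal(abs(diff(ln$x_pair)), 0.0385, tolerance = 1e-12)
})

test_that("make_vessel_tree validates its arguments", {
  expect_error(make_vessel_tree(seed = 1, field_of_view = c(-1, 1)),
               "field_of_view")
  expect_error(make_vessel_tree(seed = 1, n_roots = -1), "n_roots")
})

test_that("pulsatility waveform has unit mean and positive scale", {
  for (m in c(0, 0.3, 0.9)) {
    p <- pulsatility_profile(modulation_depth = m)
    expect_equal(mean(p$waveform), 1, tolerance = 1e-6)
    expect_true(all(p$waveform > 0))
  }
  expect_error(pulsatility_profile(1), "modulation_depth")
  p <- pulsatility_profile(0.5, cardiac_period = 0.2)
  # periodicity
  expect_equal(pulsatility_scale(p, 0.07), pulsatility_scale(p, 0.27),
               tolerance = 1e-9)
})

test_that("zero density yields an empty trajectory set", {
  ts <- sample_trajectories(straight_tree(), density = 0, n_frames = 5,
                            seed = 1)
  expect_equal(dim(ts$positions)[1], 0)
  expect_error(sample_trajectories(straight_tree(), density = -1,
                                   n_frames = 5), "density")
})

test_that("steady advection displaces scatterers by exactly v * dt", {
  tr <- straight_tree(speed = 10)            # horizontal, 10 mm/s
  ts <- sample_trajectories(tr, density = 40, n_frames = 12,
                            frame_interval = 1e-3, seed = 2)
  n <- dim(ts$positions)[1]
  expect_gt(n, 0)
  for (t in 1:11) {
    ok <- ts$alive_mask[, t] & ts$alive_mask[, t + 1]
    dx <- ts$positions[ok, t + 1, 1] - ts$positions[ok, t, 1]
    dz <- ts$positions[ok, t + 1, 2] - ts$positions[ok, t, 2]
    expect_equal(dx, rep(0.010, sum(ok)), tolerance = 1e-9)
    expect_equal(max(abs(dz)), 0, tolerance = 1e-12)
  }
})

test_that("pulsatile advection follows the stored waveform", {
  puls <- pulsatility_profile(0.5, cardiac_period = 0.2)
  tr <- straight_tree(speed = 5, x0 = 0.02, x1 = 0.78)
  nT <- 201L
  ts <- sample_trajectories(tr, density = 10, n_frames = nT,
                            frame_interval = 1e-3, pulsatility = puls,
                            seed = 3)
  i <- 1L
  dx <- diff(ts$positions[i, , 1])
  wrap <- which(!ts$alive_mask[i, -1])
  keep <- setdiff(seq_len(nT - 1L), wrap)
  expected <- 5 * pulsatility_scale(puls, (keep - 1L) * 1e-3) * 1e-3
  expect_equal(dx[keep], expected, tolerance = 1e-6)
  # advection consistency: mean speed over one full cardiac period within 2%
  expect_equal(mean(expected) / 1e-3, 5, tolerance = 0.02)
})

test_that("alive scatterer positions stay inside the lumen", {
  tr <- make_vessel_tree(seed = 9, n_roots = 1, branching_depth = 1,
                         parallel_pair = FALSE)
  ts <- sample_trajectories(tr, density = 15, n_frames = 8, seed = 4)
  n <- dim(ts$positions)[1]
  for (i in seq_len(min(n, 40))) {
    seg <- tr$segments[[ts$segment_id[i]]]
    for (t in 1:8) {
      if (!ts$alive_mask[i, t]) next
      d <- min_dist_to_polyline(ts$positions[i, t, ], seg$points)
      expect_lte(d, seg$radius + 2e-3)   # small curvature tolerance
    }
  }
})

test_that("trajectory sampling is bitwise reproducible per seed", {
  tr <- make_vessel_tree(seed = 2, n_roots = 2, branching_depth = 1)
  a <- sample_trajectories(tr, density = 30, n_frames = 6, seed = 11)
  b <- sample_trajectories(tr, density = 30, n_frames = 6, seed = 11)
  expect_identical(a$positions, b$positions)
  expect_identical(a$amplitudes, b$amplitudes)
  expect_identical(a$alive_mask, b$alive_mask)
})
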