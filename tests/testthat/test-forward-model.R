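# PSF sampling and the linear scattering forward model.

measure_fwhm_px <- function(profile) {
  # half-maximum width of a sampled 1-D kernel profile, linear interpolation
  y <- profile / max(profile)
  x <- seq_along(y)
  fwhm(vessel_profile(x, y))
}

test_that("sampled PSF matches the analytic Gaussian width", {
  p <- make_gaussian_psf(0.077, 1, 0.01)
  expect_equal(sum(p$kernel^2), 1, tolerance = 1e-12)
  expect_equal(nrow(p$kernel) %% 2, 1)
  expect_equal(ncol(p$kernel) %% 2, 1)
  lat <- p$kernel[(nrow(p$kernel) + 1) / 2, ]
  expect_equal(measure_fwhm_px(lat), 7.7, tolerance = 0.02)   # 0.077 mm / 0.01 mm
  # doubling the f-number doubles the measured lateral width
  p2 <- make_gaussian_psf(0.077, 2, 0.01)
  lat2 <- p2$kernel[(nrow(p2$kernel) + 1) / 2, ]
  expect_equal(measure_fwhm_px(lat2) / measure_fwhm_px(lat), 2,
               tolerance = 0.02)
})

test_that("PSF constructor validates inputs and warns when undersampled", {
  expect_error(make_gaussian_psf(0, 1, 0.01))
  expect_warning(make_gaussian_psf(0.077, 1, 0.05), "undersampled")
})

test_that("a block with no scatterers, clutter or noise is all zero", {
  ts <- sample_trajectories(empty_tree(), density = 0, n_frames = 4, seed = 1)
  b <- synthesize_block(ts, fixture_psf(), c(16, 16), 0, 0, seed = 1)
  expect_true(all(b$data == 0))
  expect_identical(b$kind, "raw")
})

test_that("a delta PSF reproduces a static scatterer as a pixel impulse", {
  delta <- structure(list(kernel = matrix(1, 1, 1), pixel_pitch = 0.0125,
                          wavelength = 0.077, f_number = 1,
                          fwhm_mm = c(lateral = 0.0125, axial = 0.0125),
                          sigma_px = c(lateral = 1, axial = 1)),
                     class = "psf")
  # position exactly on pixel (z = 8, x = 5) of the 0-based grid
  ts <- static_scatterer(x = 5 * 0.0125, z = 8 * 0.0125, n_frames = 3,
                         amplitude = 2.5)
  b <- synthesize_block(ts, delta, c(16, 16), 0, 0, seed = 1)
  for (t in 1:3) {
    fr <- b$data[, , t]
    expect_equal(fr[9, 6], 2.5, tolerance = 1e-12)
    expect_equal(sum(fr != 0), 1)
  }
})

test_that("the forward model is linear in the scatterer set", {
  tr <- make_vessel_tree(seed = 4, n_roots = 1, branching_depth = 1,
                         parallel_pair = FALSE)
  a <- sample_trajectories(tr, density = 20, n_frames = 4, seed = 5)
  b <- sample_trajectories(tr, density = 15, n_frames = 4, seed = 6)
  psf <- fixture_psf()
  ba <- synthesize_block(a, psf, c(64, 64), 0, 0, seed = 1)
  bb <- synthesize_block(b, psf, c(64, 64), 0, 0, seed = 1)
  bab <- synthesize_block(merge_trajectories(a, b), psf, c(64, 64), 0, 0,
                          seed = 1)
  expect_equal(bab$data, ba$data + bb$data, tolerance = 1e-10)
  # energy monotonicity: adding scatterers cannot decrease block energy
  expect_gte(block_energy(bab) + 1e-12, block_energy(ba))
  expect_gte(block_energy(bab) + 1e-12, block_energy(bb))
})

test_that("default clutter dominates the first singular value by >= 10x", {
  tr <- make_vessel_tree(seed = 4, n_roots = 2, branching_depth = 1)
  ts <- sample_trajectories(tr, density = 60, n_frames = 16, seed = 5)
  b <- synthesize_block(ts, fixture_psf(), c(64, 64),
                        clutter_amplitude = 40, noise_sigma = 0.3, seed = 6)
  sv <- svd(matrix(b$data, 64 * 64, 16), nu = 0, nv = 0)$d
  expect_gte(sv[1] / sv[2], 10)
})

test_that("scatterers outside the grid are skipped and counted", {
  ts <- static_scatterer(x = 5, z = 5, n_frames = 2)   # far outside 16 x 16
  expect_message(
    b <- synthesize_block(ts, fixture_psf(), c(16, 16), 0, 0, seed = 1),
    "skipped")
  expect_equal(b$dropped_scatterers, 2L)
  expect_true(all(b$data == 0))
})

test_that("block synthesis is reproducible per seed", {
  tr <- make_vessel_tree(seed = 4, n_roots = 1, branching_depth = 0,
                         parallel_pair = FALSE)
  ts <- sample_trajectories(tr, density = 20, n_frames = 3, seed = 5)
  b1 <- synthesize_block(ts, fixture_psf(), c(32, 32), 5, 0.1, seed = 9)
  b2 <- synthesize_block(ts, fixture_psf(), c(32, 32), 5, 0.1, seed = 9)
  expect_identical(b1$data, b2$data)
})
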