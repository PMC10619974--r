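# SVD clutter filtering, power Doppler, flow separation, temporal
# truncation/interpolation and sliding windows.

seeded_block <- function(Z = 8, X = 8, Tn = 10, seed = 1, kind = "raw") {
  d <- withr::with_seed(seed, array(rnorm(Z * X * Tn), c(Z, X, Tn)))
  b <- cspd:::new_st_block(d, 0.0125, 1000, kind)
  b
}

test_that("k = 0 SVD filtering is the identity", {
  b <- seeded_block()
  f <- svd_clutter_filter(b, svd_filter_spec(0))
  expect_equal(f$data, b$data, tolerance = 1e-10)
  expect_identical(f$kind, "clutter_filtered")
})

test_that("k = 1 annihilates a temporally static (rank-1) block", {
  img <- withr::with_seed(2, matrix(rnorm(64), 8, 8))
  b <- cspd:::new_st_block(array(rep(img, 6), c(8, 8, 6)), 0.0125, 1000)
  f <- svd_clutter_filter(b, svd_filter_spec(1))
  expect_lte(block_energy(f), 1e-10 * block_energy(b))
})

test_that("filter output energy never exceeds input energy", {
  b <- seeded_block(seed = 3)
  for (k in 0:3) {
    f <- svd_clutter_filter(b, svd_filter_spec(k))
    expect_lte(block_energy(f), block_energy(b) + 1e-9)
  }
  expect_error(svd_clutter_filter(b, svd_filter_spec(10)), "cutoff")
  expect_error(svd_clutter_filter(seeded_block(kind = "clutter_filtered")),
               "raw")
})

test_that("adaptive cutoff lands at the knee of a constructed spectrum", {
  # rank-2 strong clutter + weak noise floor
  set.seed(4)
  C <- matrix(rnorm(200 * 2), 200, 2) %*% diag(c(100, 50)) %*%
    t(qr.Q(qr(matrix(rnorm(12 * 2), 12, 2)))) + matrix(rnorm(200 * 12, 0, 0.1), 200, 12)
  b <- cspd:::new_st_block(array(C, c(20, 10, 12)), 0.0125, 1000)
  f <- svd_clutter_filter(b, svd_filter_spec("adaptive"))
  expect_equal(f$svd_cutoff, 2L)
})

test_that("power Doppler equals the per-pixel mean squared magnitude", {
  z <- cspd:::new_st_block(array(0, c(4, 4, 3)), 0.0125, 1000,
                           "clutter_filtered")
  expect_true(all(power_doppler(z)$intensity == 0))
  o <- cspd:::new_st_block(array(1, c(4, 4, 3)), 0.0125, 1000,
                           "clutter_filtered")
  expect_true(all(power_doppler(o)$intensity == 1))

  b <- seeded_block(3, 3, 4, seed = 5, kind = "clutter_filtered")
  pd <- power_doppler(b)
  # brute-force per-pixel oracle
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (t in 1:4) acc <- acc + abs(b$data[i, j, t])^2
    expect_equal(pd$intensity[i, j], acc / 4, tolerance = 1e-12)
  }
  expect_equal(pd$n_frames_used, 4)
  expect_error(power_doppler(seeded_block()), "clutter_filtered")
})

test_that("flow-band partition conserves the signal and isolates tones", {
  b <- seeded_block(4, 4, 16, seed = 6, kind = "clutter_filtered")
  one <- flow_separation_augment(b, 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$data, b$data, tolerance = 1e-10)

  bands <- flow_separation_augment(b, 4)
  total <- Reduce(`+`, lapply(bands, function(x) x$data))
  expect_equal(total, b$data, tolerance = 1e-6 * sqrt(mean(b$data^2)))

  z <- cspd:::new_st_block(array(0, c(4, 4, 16)), 0.0125, 1000,
                           "clutter_filtered")
  for (bb in flow_separation_augment(z, 4)) expect_true(all(bb$data == 0))

  # complex tone at a frequency interior to band 3 of 8 (T = 64)
  Tn <- 64L
  fshift <- 20                              # shifted bin 20 -> band 3 of 8
  f <- (fshift - 1 - 32) / Tn
  tone <- exp(2i * pi * f * (0:(Tn - 1)))
  cb <- cspd:::new_st_block(array(rep(tone, each = 4), c(2, 2, Tn)),
                            0.0125, 1000, "clutter_filtered")
  bl <- flow_separation_augment(cb, 8)
  en <- vapply(bl, block_energy, numeric(1))
  expect_gte(en[3] / sum(en), 0.99)
  expect_error(flow_separation_augment(b, 9), "n_bands")
})

test_that("truncate-and-interpolate is identity at keep_every 1 and exact on ramps", {
  b <- seeded_block(4, 4, 16, seed = 7)
  expect_identical(truncate_and_interpolate(b, 1)$data, b$data)

  # per-pixel affine slow-time ramps are reproduced exactly
  rb <- cspd:::new_st_block(
    outer(matrix(runif(16), 4, 4), seq_len(16)) + 0.3, 0.0125, 1000)
  out <- truncate_and_interpolate(rb, 4)
  expect_equal(out$data, rb$data, tolerance = 1e-10)
  expect_error(truncate_and_interpolate(b, 16), "keep_every")
})

test_that("truncate-and-interpolate matches a two-point interpolation oracle", {
  b <- seeded_block(3, 3, 17, seed = 8)
  out <- truncate_and_interpolate(b, 4)
  kept <- c(seq(1, 17, 4))
  for (i in 1:3) for (j in 1:3) {
    orc <- approx(kept, b$data[i, j, kept], xout = 1:17)$y
    expect_equal(out$data[i, j, ], orc, tolerance = 1e-12)
  }
})

test_that("sliding-window output count follows the closed form", {
  for (case in list(c(400, 200, 50), c(64, 16, 8), c(30, 30, 5),
                    c(50, 20, 7))) {
    Tn <- case[1]; w <- case[2]; s <- case[3]
    b <- seeded_block(2, 2, Tn, seed = Tn, kind = "clutter_filtered")
    r <- sliding_window_series(b, w, s)
    expect_length(r$images, floor((Tn - w) / s) + 1)
  }
  b <- seeded_block(2, 2, 12, seed = 9, kind = "clutter_filtered")
  whole <- sliding_window_series(b, 12, 4)
  expect_length(whole$images, 1)
  expect_equal(whole$images[[1]]$intensity, power_doppler(b)$intensity)
  expect_error(sliding_window_series(b, 20, 4), "window")
})

test_that("power Doppler of clutter after filtering at the clutter rank is negligible", {
  ts <- sample_trajectories(empty_tree(), density = 0, n_frames = 16, seed = 1)
  b <- synthesize_block(ts, fixture_psf(), c(32, 32),
                        clutter_amplitude = 40, noise_sigma = 0, seed = 2,
                        clutter_walk_sd = 0.02)
  raw_pd <- mean(apply(b$data^2, c(1, 2), mean))
  f <- svd_clutter_filter(b, svd_filter_spec(2))
  expect_lte(mean(power_doppler(f)$intensity), 0.01 * raw_pd)
})
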