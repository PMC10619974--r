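# Localization and super-resolved accumulation.

test_that("blank frames yield no detections", {
  psf <- fixture_psf()
  expect_equal(nrow(localize_frame(matrix(0, 32, 32), psf)), 0)
  expect_error(localize_frame(matrix(0, 32, 32), psf, 1.5),
               "detection_threshold")
})

test_that("a noiseless scatterer is localized to < 0.1 pixel", {
  psf <- fixture_psf()
  pitch <- psf$pixel_pitch
  offsets <- c(0, 0.17, 0.33, 0.5, -0.42)
  for (off in offsets) {
    x_true <- (15 + off) * pitch
    z_true <- (17 - off / 2) * pitch
    ts <- static_scatterer(x_true, z_true)
    b <- synthesize_block(ts, psf, c(32, 32), 0, 0, seed = 1)
    loc <- localize_frame(b$data[, , 1], psf, 0.3)
    expect_equal(nrow(loc), 1)
    expect_lt(abs(loc$x - x_true) / pitch, 0.1)
    expect_lt(abs(loc$z - z_true) / pitch, 0.1)
  }
})

test_that("well-separated scatterers are each recovered", {
  psf <- fixture_psf()
  pitch <- psf$pixel_pitch
  sep_px <- 3 * psf$fwhm_mm["lateral"] / pitch   # 3x the lateral FWHM
  p1 <- c(12.3, 20.0) * pitch
  p2 <- c(12.3 + sep_px, 20.0) * pitch
  pos <- array(NA_real_, c(2, 1, 2))
  pos[, 1, 1] <- c(p1[1], p2[1]); pos[, 1, 2] <- c(p1[2], p2[2])
  ts <- structure(list(positions = pos, amplitudes = c(1, 1),
                       alive_mask = matrix(TRUE, 2, 1),
                       frame_interval = 1e-3, segment_id = c(1L, 1L),
                       segment_speed = c(0, 0),
                       pulsatility = pulsatility_profile(0), seed = NA),
                  class = "trajectory_set")
  b <- synthesize_block(ts, psf, c(44, 44), 0, 0, seed = 1)
  loc <- localize_frame(b$data[, , 1], psf, 0.3)
  expect_equal(nrow(loc), 2)
  loc <- loc[order(loc$x), ]
  expect_lt(abs(loc$x[1] - p1[1]) / pitch, 0.2)
  expect_lt(abs(loc$x[2] - p2[1]) / pitch, 0.2)
  expect_lt(abs(loc$z[1] - p1[2]) / pitch, 0.2)
})

test_that("localization error grows with electronic noise", {
  psf <- fixture_psf()
  pitch <- psf$pixel_pitch
  err_at <- function(sigma) {
    errs <- c()
    for (k in 1:8) {
      off <- (k - 4.5) / 9
      x_true <- (14 + off) * pitch; z_true <- (16 - off) * pitch
      b <- synthesize_block(static_scatterer(x_true, z_true, amplitude = 5),
                            psf, c(32, 32), 0, sigma, seed = 100 + k)
      loc <- localize_frame(b$data[, , 1], psf, 0.4)
      if (nrow(loc) >= 1) {
        i <- which.max(loc$amplitude)
        errs <- c(errs, sqrt((loc$x[i] - x_true)^2 + (loc$z[i] - z_true)^2) / pitch)
      }
    }
    mean(errs)
  }
  e0 <- err_at(0)
  e2 <- err_at(0.15)
  expect_lt(e0, 0.1)
  expect_gt(e2, e0)
})

test_that("accumulation conserves event counts exactly", {
  empty <- data.frame(frame = integer(0), x = numeric(0), z = numeric(0),
                      amplitude = numeric(0))
  u0 <- accumulate_ulm(empty, c(16, 16), R = 4, pixel_pitch = 0.0125)
  expect_true(all(u0$counts == 0))

  seven <- data.frame(frame = 1:7, x = rep(0.1, 7), z = rep(0.12, 7),
                      amplitude = 1)
  u7 <- accumulate_ulm(seven, c(16, 16), R = 4, pixel_pitch = 0.0125)
  expect_equal(max(u7$counts), 7)
  expect_equal(sum(u7$counts), 7)
  expect_equal(sum(u7$counts > 0), 1)

  ev <- withr::with_seed(10, data.frame(
    frame = 1:1000,
    x = runif(1000, 0, 15 * 0.0125),
    z = runif(1000, 0, 15 * 0.0125),
    amplitude = 1))
  u <- accumulate_ulm(ev, c(16, 16), R = 4, pixel_pitch = 0.0125)
  expect_equal(sum(u$counts), 1000)
  expect_equal(u$R, 4L)
  expect_equal(u$pixel_pitch, 0.0125 / 4)
})

test_that("out-of-grid events are dropped with a count", {
  ev <- data.frame(frame = 1:2, x = c(0.05, 5), z = c(0.05, 5), amplitude = 1)
  expect_message(
    u <- accumulate_ulm(ev, c(16, 16), R = 2, pixel_pitch = 0.0125),
    "dropped")
  expect_equal(sum(u$counts), 1)
  expect_equal(u$dropped, 1L)
})

test_that("ULM normalization saturates at the 99th percentile of nonzero counts", {
  u <- accumulate_ulm(data.frame(frame = 1, x = 0.1, z = 0.1, amplitude = 1),
                      c(16, 16), R = 1, pixel_pitch = 0.0125)
  u$counts[2, 2] <- 50
  u$counts[3, 3] <- 1
  un <- normalize_ulm(u)
  expect_equal(max(un$intensity), 1)
  expect_true(all(un$intensity >= 0 & un$intensity <= 1))
  z <- normalize_ulm(accumulate_ulm(
    data.frame(frame = integer(0), x = numeric(0), z = numeric(0),
               amplitude = numeric(0)), c(8, 8), 1, 0.0125))
  expect_true(all(z$intensity == 0))
})

test_that("a zero-vessel plane yields an all-zero ULM target", {
  cfg <- training_pair_config(n_blocks = 2, block_frames = 8,
                              ulm_frames = 60, ulm_chunk = 30)
  pr <- make_training_pair(empty_tree(), cfg, seed = 5)
  expect_true(all(pr$ulm$counts == 0))
  expect_length(pr$blocks, 2)
  # blocks still contain clutter + noise energy
  expect_gt(block_energy(pr$blocks[[1]]), 0)
})

test_that("training-pair configuration validates the frame budget", {
  expect_error(training_pair_config(block_frames = 100, ulm_frames = 50),
               "ulm_frames")
})
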