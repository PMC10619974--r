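# Closed forms and independent oracles for the evaluation metrics.

test_that("psnr matches its closed forms and the direct formula", {
  a <- matrix(0.4, 8, 8)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 0.1), 20, tolerance = 1e-12)
  set.seed(1)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  expect_equal(psnr(x, y), -10 * log10(mean((x - y)^2)), tolerance = 1e-12)
  expect_error(psnr(x, matrix(0, 4, 4)), "shape")
})

ssim_reference <- function(a, b, sigma = 1.0) {
  # independent sliding-window implementation (explicit loops)
  h <- 1L
  g <- outer(exp(-((-h:h)^2) / (2 * sigma^2)), exp(-((-h:h)^2) / (2 * sigma^2)))
  c1 <- 0.01^2; c2 <- 0.03^2
  n <- nrow(a); m <- ncol(a)
  out <- matrix(NA_real_, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc_w <- 0; mu_a <- 0; mu_b <- 0; qa <- 0; qb <- 0; qab <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n || jj < 1 || jj > m) next
      w <- g[di + 2, dj + 2]
      acc_w <- acc_w + w
      mu_a <- mu_a + w * a[ii, jj]; mu_b <- mu_b + w * b[ii, jj]
      qa <- qa + w * a[ii, jj]^2; qb <- qb + w * b[ii, jj]^2
      qab <- qab + w * a[ii, jj] * b[ii, jj]
    }
    mu_a <- mu_a / acc_w; mu_b <- mu_b / acc_w
    va <- qa / acc_w - mu_a^2; vb <- qb / acc_w - mu_b^2
    vab <- qab / acc_w - mu_a * mu_b
    out[i, j] <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  }
  mean(out)
}

test_that("ssim satisfies its identities and matches a windowed oracle", {
  set.seed(2)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_true(ssim(a, b) >= -1 && ssim(a, b) <= 1)
  expect_equal(ssim(a, b), ssim_reference(a, b), tolerance = 1e-6)
  expect_error(ssim(a, matrix(0, 4, 4)), "shape")
})

test_that("fwhm matches analytic Gaussian and triangular widths", {
  x <- seq(-150, 150, by = 2.5)
  g <- exp(-x^2 / (2 * 20^2))
  expect_equal(fwhm(vessel_profile(x, g)), 2 * sqrt(2 * log(2)) * 20,
               tolerance = 0.02)
  # triangle rising over w and falling over w has FWHM exactly w
  w <- 40
  xt <- seq(-w, w, by = 1)
  tri <- pmax(0, 1 - abs(xt) / w)
  expect_equal(fwhm(vessel_profile(xt, tri)), w, tolerance = 1e-9)
  expect_error(fwhm(vessel_profile(1:10, rep(1, 10))), "flat")
  # scale equivariance
  p1 <- fwhm(vessel_profile(x, g))
  p3 <- fwhm(vessel_profile(3 * x, g))
  expect_equal(p3 / p1, 3, tolerance = 1e-9)
})

test_that("mse_nip matches its analytic value and a direct recomputation", {
  pos <- 1:6
  a <- c(0, 1, 1, 1, 0, 1)
  b <- c(0, 1, 0.5, 0.5, 0.5, 1)
  expect_equal(mse_nip(vessel_profile(pos, a, "longitudinal"),
                       vessel_profile(pos, b, "longitudinal")),
               0.125, tolerance = 1e-12)
  expect_equal(mse_nip(vessel_profile(pos, a, "longitudinal"),
                       vessel_profile(pos, a, "longitudinal")), 0)
  set.seed(3)
  ya <- runif(20); yb <- runif(20)
  m <- mse_nip(vessel_profile(1:20, ya), vessel_profile(1:20, yb))
  nrm <- function(v) (v - min(v)) / (max(v) - min(v))
  expect_equal(m, mean((nrm(ya) - nrm(yb))^2), tolerance = 1e-12)
  expect_error(mse_nip(vessel_profile(1:5, runif(5)),
                       vessel_profile(11:15, runif(5))), "overlap")
})

test_that("fourier resolution is self-consistent and orders blur levels", {
  set.seed(4)
  base <- matrix(runif(64 * 64), 64, 64)
  gk <- function(sig) {
    h <- ceiling(3 * sig)
    k <- outer(exp(-((-h:h)^2) / (2 * sig^2)), exp(-((-h:h)^2) / (2 * sig^2)))
    k / sum(k)
  }
  pd <- cspd:::conv2_same(base, gk(3))
  lambda_um <- 150
  expect_equal(fourier_resolution(pd, pd, lambda_um, 12.5), lambda_um,
               tolerance = 1e-6)
  sharp <- cspd:::conv2_same(base, gk(1.5))
  r_sharp <- fourier_resolution(pd, sharp, lambda_um, 12.5)
  expect_lt(r_sharp, lambda_um)
})

test_that("evaluate_pair aggregates finite metrics and honors identities", {
  set.seed(5)
  ulm_mat <- matrix(0, 64, 64)
  ulm_mat[20:22, ] <- 1
  gen <- structure(list(intensity = ulm_mat, pixel_pitch = 0.0125 / 4, R = 4L),
                   class = "cspd_image")
  ulm <- structure(list(counts = ulm_mat, intensity = ulm_mat, R = 4L,
                        pixel_pitch = 0.0125 / 4, n_events = sum(ulm_mat)),
                   class = "ulm_image")
  pd_int <- cspd:::conv2_same(ulm_mat[seq(1, 64, 4), seq(1, 64, 4)] + 0.01,
                              cspd:::gaussian_window(3, 1))
  pd <- structure(list(intensity = pd_int, pixel_pitch = 0.0125,
                       n_frames_used = 10), class = "power_doppler_image")
  lines <- list(
    list(p0 = c(0.04, 0.02), p1 = c(0.04, 0.14), orientation = "cross"),
    list(p0 = c(0.01, 0.065), p1 = c(0.15, 0.065), orientation = "longitudinal"))
  rep <- evaluate_pair(gen, ulm, pd, lines)
  expect_s3_class(rep, "metrics_report")
  expect_identical(rep$psnr, Inf)              # generated equals the target
  expect_equal(rep$ssim, 1, tolerance = 1e-12)
  expect_equal(rep$mse_nip_mean, 0, tolerance = 1e-12)
  expect_true(is.finite(rep$ssim_pd))
  expect_true(all(rep$fwhm_gen_um > 0, na.rm = TRUE))
})
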