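# Quantitative evaluation: PSNR, SSIM (3x3 Gaussian window), vessel
# cross-section FWHM and FWHM ratio, mean squared error of normalized
# longitudinal intensity profiles (MSE-NIP), and Fourier-domain global
# resolution from iso-frequency curves. All metrics operate on the linear
# intensity scale of images normalized to [0, 1].

#' Peak signal-to-noise ratio
#'
#' `PSNR = -10 log10(MSE(a, b))` for images normalized to `[0, 1]` (the
#' peak is 1, so the familiar `20 log10(MAX)` term vanishes). Identical
#' images return `Inf`.
#'
#' @param a,b same-shape numeric matrices/arrays in `[0, 1]`.
#' @return PSNR in dB (`Inf` when `a == b`).
#' @export
#' @examples
#' psnr(matrix(0.5, 4, 4), matrix(0.6, 4, 4))  # 20 dB
psnr <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_invalid("`a` and `b` must have the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}

gaussian_window <- function(size = 3L, sigma = 1.0) {
  h <- (size - 1L) / 2
  g <- outer(exp(-((-h:h)^2) / (2 * sigma^2)), exp(-((-h:h)^2) / (2 * sigma^2)))
  g / sum(g)
}

# "same" convolution with border renormalization (window weights that fall
# outside the image are excluded and the remaining weights rescaled).
conv2_norm <- function(img, w) {
  num <- conv2_same(img, w)
  den <- conv2_same(matrix(1, nrow(img), ncol(img)), w)
  num / den
}

#' Structural similarity index
#'
#' Local means, variances and covariance are computed with a 3x3 Gaussian
#' window (sigma 1.0, border-renormalized); the SSIM map
#' `((2 mu_a mu_b + c1)(2 sigma_ab + c2)) /
#'  ((mu_a^2 + mu_b^2 + c1)(sigma_a^2 + sigma_b^2 + c2))`
#' is averaged to a scalar. The stability constants are
#' `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` with dynamic range `L = 1` on
#' normalized images.
#'
#' @param a,b same-shape matrices in `[0, 1]`.
#' @param window_size,sigma Gaussian window parameters.
#' @return SSIM in `[-1, 1]`; `ssim(a, a) == 1`.
#' @export
ssim <- function(a, b, window_size = 3L, sigma = 1.0) {
  if (!all(dim(a) == dim(b))) stop_invalid("`a` and `b` must have the same shape")
  w <- gaussian_window(window_size, sigma)
  c1 <- 0.01^2
  c2 <- 0.03^2
  mu_a <- conv2_norm(a, w)
  mu_b <- conv2_norm(b, w)
  va <- conv2_norm(a^2, w) - mu_a^2
  vb <- conv2_norm(b^2, w) - mu_b^2
  vab <- conv2_norm(a * b, w) - mu_a * mu_b
  m <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(m)
}

#' Vessel intensity profile
#'
#' A 1-D intensity profile sampled along a line (cross-sectional or
#' longitudinal to a vessel).
#'
#' @param positions sample positions along the line, micrometers.
#' @param intensities nonnegative linear-scale intensities.
#' @param orientation `"cross"` or `"longitudinal"`.
#' @return object of class `vessel_profile`.
#' @export
vessel_profile <- function(positions, intensities,
                           orientation = c("cross", "longitudinal")) {
  orientation <- match.arg(orientation)
  if (length(positions) < 5L) stop_invalid("a profile needs at least 5 samples")
  if (any(intensities < 0)) stop_invalid("intensities must be nonnegative")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 orientation = orientation),
            class = "vessel_profile")
}

#' Full width at half maximum of a profile
#'
#' Min-max normalizes the profile on the linear scale, locates the unique
#' interior maximum, and finds the half-maximum crossings on each side by
#' linear interpolation between samples.
#'
#' @param profile a [vessel_profile()] (or a plain list with `positions`
#'   and `intensities`).
#' @return FWHM in the units of `positions`.
#' @export
#' @examples
#' x <- seq(-100, 100, by = 2)
#' fwhm(vessel_profile(x, exp(-x^2 / (2 * 20^2))))  # ~47.1
fwhm <- function(profile) {
  p <- profile$positions
  y <- profile$intensities
  rng <- range(y)
  if (rng[2] <= rng[1]) {
    stop_invalid("flat profile: no half-maximum crossings (boundary-truncated)")
  }
  y <- (y - rng[1]) / (rng[2] - rng[1])
  im <- which.max(y)
  if (im == 1L || im == length(y)) {
    stop_invalid("profile maximum lies on the boundary (boundary-truncated)")
  }
  half_cross <- function(idx_seq) {
    # walk outward from the peak until the profile drops below 1/2
    for (k in seq_along(idx_seq)[-1]) {
      i0 <- idx_seq[k - 1L]; i1 <- idx_seq[k]
      if (y[i1] <= 0.5 && y[i0] > 0.5) {
        return(p[i0] + (0.5 - y[i0]) * (p[i1] - p[i0]) / (y[i1] - y[i0]))
      }
    }
    NA_real_
  }
  left <- half_cross(seq(im, 1L))
  right <- half_cross(seq(im, length(y)))
  if (is.na(left) || is.na(right)) {
    stop_invalid("no half-maximum crossing on one side (boundary-truncated)")
  }
  abs(right - left)
}

#' MSE of normalized intensity profiles
#'
#' Resamples the second profile onto the positions of the first (over their
#' overlapping range), min-max normalizes each to `[0, 1]`, and returns the
#' mean squared difference. Used on longitudinal vessel profiles to assess
#' intensity-distribution consistency between reconstructions.
#'
#' @param profile_a,profile_b [vessel_profile()] objects.
#' @return dimensionless mean squared error.
#' @export
mse_nip <- function(profile_a, profile_b) {
  ra <- range(profile_a$positions)
  rb <- range(profile_b$positions)
  lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
  if (hi <= lo) stop_invalid("profiles do not overlap in position")
  keep <- profile_a$positions >= lo & profile_a$positions <= hi
  pa <- profile_a$positions[keep]
  ya <- profile_a$intensities[keep]
  yb <- stats::approx(profile_b$positions, profile_b$intensities, xout = pa)$y
  nrm <- function(v) {
    r <- range(v)
    if (r[2] <= r[1]) return(v * 0)
    (v - r[1]) / (r[2] - r[1])
  }
  mean((nrm(ya) - nrm(yb))^2)
}

# radially averaged 2-D spectral magnitude: mean magnitude on 1-pixel rings
iso_frequency_curve <- function(image, pixel_pitch_um) {
  Z <- nrow(image); X <- ncol(image)
  S <- Mod(stats::fft(image))
  # fftshift
  S <- S[c((floor(Z / 2) + 1L):Z, 1:floor(Z / 2)),
         c((floor(X / 2) + 1L):X, 1:floor(X / 2))]
  cz <- floor(Z / 2) + 1L; cx <- floor(X / 2) + 1L
  rz <- (seq_len(Z) - cz); rx <- (seq_len(X) - cx)
  rr <- sqrt(outer(rz^2, rx^2, "+"))
  ring <- round(rr)
  nmax <- floor(min(Z, X) / 2) - 1L
  # ring 0 (the DC component) is excluded: it only reflects the image mean
  # and would dominate the exponential fit
  amp <- vapply(1:nmax, function(r) mean(S[ring == r]), numeric(1))
  freq <- (1:nmax) / (min(Z, X) * pixel_pitch_um)   # cycles per um
  list(freq = freq, amp = amp)
}

# least-squares exponential fit amp = A exp(-b f) + c on the linear curve
fit_exponential <- function(freq, amp) {
  c0 <- min(amp) * 0.5
  pos <- pmax(amp - c0, max(amp) * 1e-6)
  lm0 <- stats::lm(log(pos) ~ freq)
  start <- c(A = exp(stats::coef(lm0)[[1]]), b = -stats::coef(lm0)[[2]], c = c0)
  sse <- function(par) {
    pr <- par[1] * exp(-par[2] * freq) + par[3]
    sum((pr - amp)^2)
  }
  opt <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- unname(opt$par)
  if (par[2] <= 0) stop_invalid("iso-frequency curve is non-decreasing: exponential fit failed")
  list(A = par[1], b = par[2], c = par[3])
}

#' Fourier-domain global resolution
#'
#' Computes the iso-frequency curve (radially averaged 2-D spectral
#' magnitude) of the reference power Doppler image and of the test image,
#' fits `A exp(-b f) + c` to each, reads the reference amplitude off the
#' power Doppler fit at the one-wavelength spatial frequency `1 / lambda`,
#' and returns `1 / f*` where the test image's fitted curve reaches that
#' same amplitude. By construction the power Doppler image itself scores
#' `lambda`; a sharper image reaches the reference amplitude at a higher
#' spatial frequency, i.e. a smaller (finer) resolution.
#'
#' @param image_ref_pd reference power Doppler image (matrix, linear
#'   scale), already on the same grid as `image_test`.
#' @param image_test image under evaluation (matrix, same grid).
#' @param wavelength_um acoustic wavelength in micrometers.
#' @param pixel_pitch_um pixel pitch of the common grid in micrometers.
#' @return resolution in micrometers.
#' @export
fourier_resolution <- function(image_ref_pd, image_test, wavelength_um,
                               pixel_pitch_um) {
  if (!all(dim(image_ref_pd) == dim(image_test))) {
    stop_invalid("images must share a grid")
  }
  if (wavelength_um <= 0 || pixel_pitch_um <= 0) {
    stop_invalid("`wavelength_um` and `pixel_pitch_um` must be > 0")
  }
  ref <- iso_frequency_curve(image_ref_pd / max(image_ref_pd), pixel_pitch_um)
  tst <- iso_frequency_curve(image_test / max(image_test), pixel_pitch_um)
  fit_ref <- fit_exponential(ref$freq, ref$amp)
  fit_tst <- fit_exponential(tst$freq, tst$amp)
  f_lambda <- 1 / wavelength_um
  a_ref <- fit_ref$A * exp(-fit_ref$b * f_lambda) + fit_ref$c
  if (a_ref <= fit_tst$c) {
    # the test spectrum floor sits above the reference amplitude: resolution
    # beyond the measurable band
    stop_invalid("reference amplitude below the test curve floor: resolution not measurable")
  }
  f_star <- -log((a_ref - fit_tst$c) / fit_tst$A) / fit_tst$b
  if (!is.finite(f_star) || f_star <= 0) {
    stop_invalid("exponential fit produced no valid intersection")
  }
  1 / f_star
}

#' Sample an image profile along a line
#'
#' Bilinear interpolation of an image along the segment from `p0` to `p1`
#' (positions in mm on the image's pixel-centered grid).
#'
#' @param image matrix (rows axial z, columns lateral x).
#' @param pixel_pitch grid pitch in mm.
#' @param p0,p1 numeric length-2 `(x, z)` endpoints in mm.
#' @param n number of samples.
#' @param orientation passed to [vessel_profile()].
#' @return a [vessel_profile()] with positions in micrometers.
#' @export
extract_profile <- function(image, pixel_pitch, p0, p1, n = 64L,
                            orientation = "cross") {
  tseq <- seq(0, 1, length.out = n)
  xs <- p0[1] + tseq * (p1[1] - p0[1])
  zs <- p0[2] + tseq * (p1[2] - p0[2])
  fx <- xs / pixel_pitch; fz <- zs / pixel_pitch
  Z <- nrow(image); X <- ncol(image)
  fx <- pmin(pmax(fx, 0), X - 1 - 1e-9)
  fz <- pmin(pmax(fz, 0), Z - 1 - 1e-9)
  ix <- floor(fx); iz <- floor(fz)
  wx <- fx - ix; wz <- fz - iz
  v <- image[cbind(iz + 1L, ix + 1L)] * (1 - wz) * (1 - wx) +
    image[cbind(iz + 2L, ix + 1L)] * wz * (1 - wx) +
    image[cbind(iz + 1L, ix + 2L)] * (1 - wz) * wx +
    image[cbind(iz + 2L, ix + 2L)] * wz * wx
  dist_um <- 1e3 * tseq * sqrt(sum((p1 - p0)^2))
  vessel_profile(dist_um, pmax(v, 0), orientation)
}

#' Bilinear upsampling of an image by an integer factor
#'
#' Grid reconciliation helper: brings a native-grid power Doppler image
#' onto the R-fold super-resolved grid for pixelwise comparison.
#'
#' @param image matrix.
#' @param R integer factor (power of 2 uses the network's bilinear stages;
#'   other factors use separable linear interpolation).
#' @return `R*Z x R*X` matrix.
#' @export
upsample_bilinear <- function(image, R) {
  R <- as.integer(R)
  if (R == 1L) return(image)
  if (bitwAnd(R, R - 1L) == 0L) {
    x <- array(image, c(dim(image), 1L))
    x <- upsample_pow2_fwd(x, as.integer(log2(R)))$y[, , 1]
    return(x)
  }
  Z <- nrow(image); X <- ncol(image)
  src_r <- ((seq_len(Z * R) - 0.5) / R) - 0.5
  src_c <- ((seq_len(X * R) - 0.5) / R) - 0.5
  interp_axis <- function(m, src) {
    idx <- pmin(pmax(floor(src), 0), nrow(m) - 1)
    w <- pmin(pmax(src - idx, 0), 1)
    hi <- pmin(idx + 1, nrow(m) - 1)
    m[idx + 1L, , drop = FALSE] * (1 - w) + m[hi + 1L, , drop = FALSE] * w
  }
  out <- interp_axis(image, src_r)
  t(interp_axis(t(out), src_c))
}

#' Count resolved peaks in an intensity profile
#'
#' Smooths the profile with a short moving average, then counts local
#' maxima that are at least `height` of the profile maximum and separated
#' from neighboring counted peaks by a valley at least `prominence` below
#' the lower of the two peaks. Used to decide whether a two-vessel
#' cross-profile is resolved (two modes) or diffraction-merged (one).
#'
#' @param intensities numeric profile samples.
#' @param height minimum peak height as a fraction of the profile maximum.
#' @param prominence minimum valley depth between adjacent peaks (fraction
#'   of the profile maximum).
#' @param smooth moving-average half-width in samples (keep the smoothing
#'   window well below the expected peak separation).
#' @return integer number of resolved modes.
#' @export
count_profile_modes <- function(intensities, height = 0.5, prominence = 0.1,
                                smooth = 1L) {
  y <- as.numeric(intensities)
  if (smooth > 0L) {
    k <- rep(1, 2L * smooth + 1L)
    pad <- c(rep(y[1], smooth), y, rep(y[length(y)], smooth))
    y <- as.numeric(stats::filter(pad, k / sum(k), sides = 2))[smooth + seq_along(intensities)]
  }
  y <- y / max(y)
  n <- length(y)
  pk <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  pk <- pk[y[pk] >= height]
  if (length(pk) <= 1L) return(length(pk))
  keep <- pk[1]
  for (p in pk[-1]) {
    prev <- keep[length(keep)]
    valley <- min(y[prev:p])
    if (valley <= min(y[prev], y[p]) - prominence) {
      keep <- c(keep, p)
    } else if (y[p] > y[prev]) {
      keep[length(keep)] <- p
    }
  }
  length(keep)
}

#' Aggregate metrics for one reconstructed/reference image pair
#'
#' Computes PSNR and SSIM between the generated image and the ULM
#' reference (both min-max normalized), per-vessel FWHM ratios
#' (power Doppler FWHM / generated FWHM on cross-sectional lines),
#' per-vessel MSE-NIP (generated vs ULM on longitudinal lines), and the
#' Fourier-domain resolutions of the generated and ULM images against the
#' power Doppler reference. Per-vessel metrics are reported as mean and
#' standard deviation across the supplied lines.
#'
#' @param generated `cspd_image` (or matrix on the R-grid).
#' @param ulm `ulm_image` with `intensity` set (or matrix).
#' @param pd `power_doppler_image` (native grid; upsampled bilinearly).
#' @param vessel_lines list of lines, each a list with `p0`, `p1` (mm,
#'   native-grid coordinates) and `orientation` (`"cross"` or
#'   `"longitudinal"`).
#' @param wavelength_um wavelength for [fourier_resolution()]; `NULL`
#'   skips the Fourier metric.
#' @return object of class `metrics_report`.
#' @export
evaluate_pair <- function(generated, ulm, pd, vessel_lines = list(),
                          wavelength_um = NULL) {
  gen <- if (inherits(generated, "cspd_image")) generated$intensity else generated
  ulm_int <- if (inherits(ulm, "ulm_image")) ulm$intensity else ulm
  pd_int <- if (inherits(pd, "power_doppler_image")) pd$intensity else pd
  R <- nrow(gen) / nrow(pd_int)
  if (R != round(R)) stop_invalid("generated grid is not an integer multiple of the PD grid")
  pd_up <- upsample_bilinear(pd_int, as.integer(R))
  nrm <- function(m) {
    r <- range(m)
    if (r[2] <= r[1]) return(m * 0)
    (m - r[1]) / (r[2] - r[1])
  }
  gen_n <- nrm(gen); ulm_n <- nrm(ulm_int); pd_n <- nrm(pd_up)
  fine_pitch <- if (inherits(generated, "cspd_image")) generated$pixel_pitch else NA_real_

  fwhm_pd <- c(); fwhm_gen <- c(); nip <- c()
  for (ln in vessel_lines) {
    if (identical(ln$orientation, "cross")) {
      pr_pd <- extract_profile(pd_n, fine_pitch, ln$p0, ln$p1, orientation = "cross")
      pr_gen <- extract_profile(gen_n, fine_pitch, ln$p0, ln$p1, orientation = "cross")
      f_pd <- tryCatch(fwhm(pr_pd), error = function(e) NA_real_)
      f_gen <- tryCatch(fwhm(pr_gen), error = function(e) NA_real_)
      fwhm_pd <- c(fwhm_pd, f_pd)
      fwhm_gen <- c(fwhm_gen, f_gen)
    } else {
      pr_gen <- extract_profile(gen_n, fine_pitch, ln$p0, ln$p1,
                                orientation = "longitudinal")
      pr_ulm <- extract_profile(ulm_n, fine_pitch, ln$p0, ln$p1,
                                orientation = "longitudinal")
      nip <- c(nip, mse_nip(pr_gen, pr_ulm))
    }
  }
  ratio <- fwhm_pd / fwhm_gen
  fr_gen <- fr_ulm <- NA_real_
  if (!is.null(wavelength_um)) {
    pitch_um <- 1e3 * fine_pitch
    fr_gen <- tryCatch(fourier_resolution(pd_n, gen_n, wavelength_um, pitch_um),
                       error = function(e) NA_real_)
    fr_ulm <- tryCatch(fourier_resolution(pd_n, ulm_n, wavelength_um, pitch_um),
                       error = function(e) NA_real_)
  }
  structure(list(
    psnr = psnr(gen_n, ulm_n),
    ssim = ssim(gen_n, ulm_n),
    ssim_pd = ssim(pd_n, ulm_n),
    psnr_pd = psnr(pd_n, ulm_n),
    fwhm_pd_um = fwhm_pd, fwhm_gen_um = fwhm_gen,
    fwhm_ratio = ratio,
    fwhm_ratio_mean = mean(ratio, na.rm = TRUE),
    fwhm_ratio_sd = stats::sd(ratio[!is.na(ratio)]),
    mse_nip = nip,
    mse_nip_mean = if (length(nip)) mean(nip) else NA_real_,
    mse_nip_sd = if (length(nip) > 1) stats::sd(nip) else NA_real_,
    fourier_resolution_gen_um = fr_gen,
    fourier_resolution_ulm_um = fr_ulm),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("CS-PD evaluation metrics\n")
  cat(sprintf("  SSIM  %.4f (PD baseline %.4f)\n", x$ssim, x$ssim_pd))
  cat(sprintf("  PSNR  %.2f dB (PD baseline %.2f dB)\n", x$psnr, x$psnr_pd))
  if (length(x$fwhm_ratio) && any(!is.na(x$fwhm_ratio))) {
    cat(sprintf("  FWHM ratio (PD/CS-PD)  %.3f +/- %.3f over %d vessels\n",
                x$fwhm_ratio_mean, x$fwhm_ratio_sd %||% NA,
                sum(!is.na(x$fwhm_ratio))))
  }
  if (!is.na(x$mse_nip_mean)) {
    cat(sprintf("  MSE-NIP  %.4f +/- %.4f\n", x$mse_nip_mean,
                x$mse_nip_sd %||% NA))
  }
  if (!is.na(x$fourier_resolution_gen_um)) {
    cat(sprintf("  Fourier resolution  CS-PD %.1f um | ULM %.1f um\n",
                x$fourier_resolution_gen_um, x$fourier_resolution_ulm_um))
  }
  invisible(x)
}
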