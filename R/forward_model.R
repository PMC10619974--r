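# Linear forward model: each scatterer deposits its echogenicity times the
# system point-spread function at its (subpixel) location, on top of a
# quasi-static tissue clutter field and additive electronic noise. This is
# the standard convolutional model of post-beamforming ultrafast ultrasound
# data.

#' Anisotropic Gaussian point-spread function
#'
#' Parametric stand-in for the imaging system PSF. The lateral full width at
#' half maximum follows the diffraction limit `wavelength * f_number`; the
#' axial FWHM uses `wavelength / 2` as a pulse-length proxy (a two-cycle
#' short pulse). The kernel is sampled on the pixel grid with odd extent
#' (+/- 3 sigma) and unit energy (sum of squares 1).
#'
#' @param wavelength acoustic wavelength in mm (0.077 mm at 20 MHz in soft
#'   tissue).
#' @param f_number receive f-number (dimensionless).
#' @param pixel_pitch grid pitch in mm per pixel (isotropic).
#' @return object of class `psf`: `kernel` (Z x X matrix), `pixel_pitch`,
#'   `wavelength`, `fwhm_mm` (named lateral/axial), `sigma_px`.
#' @export
#' @examples
#' p <- make_gaussian_psf(0.077, 1, 0.0125)
#' sum(p$kernel^2)  # 1
make_gaussian_psf <- function(wavelength, f_number, pixel_pitch) {
  if (wavelength <= 0 || f_number <= 0 || pixel_pitch <= 0) {
    stop_invalid("`wavelength`, `f_number` and `pixel_pitch` must all be > 0")
  }
  fwhm_lat <- wavelength * f_number
  fwhm_ax <- wavelength / 2
  if (pixel_pitch > min(fwhm_lat, fwhm_ax) / 2) {
    warning("pixel pitch coarser than half the PSF FWHM: the sampled PSF is undersampled",
            call. = FALSE)
  }
  k <- 2 * sqrt(2 * log(2))
  sig_lat <- fwhm_lat / k / pixel_pitch   # in pixels
  sig_ax <- fwhm_ax / k / pixel_pitch
  hx <- max(1L, ceiling(3 * sig_lat))
  hz <- max(1L, ceiling(3 * sig_ax))
  gx <- exp(-((-hx:hx)^2) / (2 * sig_lat^2))
  gz <- exp(-((-hz:hz)^2) / (2 * sig_ax^2))
  kern <- outer(gz, gx)                   # rows axial (z), cols lateral (x)
  kern <- kern / sqrt(sum(kern^2))
  structure(list(kernel = kern, pixel_pitch = pixel_pitch,
                 wavelength = wavelength, f_number = f_number,
                 fwhm_mm = c(lateral = fwhm_lat, axial = fwhm_ax),
                 sigma_px = c(lateral = sig_lat, axial = sig_ax)),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  cat(sprintf("Gaussian PSF: lateral FWHM %.1f um, axial FWHM %.1f um, %d x %d taps @ %.1f um pitch\n",
              1e3 * x$fwhm_mm[1], 1e3 * x$fwhm_mm[2],
              nrow(x$kernel), ncol(x$kernel), 1e3 * x$pixel_pitch))
  invisible(x)
}

new_st_block <- function(data, pixel_pitch, frame_rate, kind = "raw") {
  structure(list(data = data, pixel_pitch = pixel_pitch,
                 frame_rate = frame_rate, kind = kind,
                 dropped_scatterers = 0L),
            class = "st_block")
}

#' @export
print.st_block <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Spatiotemporal block: %d x %d x %d (%s, %s), %.1f um pitch, %g Hz\n",
              d[1], d[2], d[3], x$kind,
              if (is.complex(x$data)) "complex" else "magnitude",
              1e3 * x$pixel_pitch, x$frame_rate))
  invisible(x)
}

# 2-D "same" convolution via FFT (complex-safe). Kernel extent must be odd.
conv2_same <- function(img, kern) {
  Z <- nrow(img); X <- ncol(img)
  kz <- nrow(kern); kx <- ncol(kern)
  if (kz == 1L && kx == 1L) return(img * kern[1, 1])
  hz <- (kz - 1L) %/% 2L; hx <- (kx - 1L) %/% 2L
  PZ <- Z + kz - 1L; PX <- X + kx - 1L
  pi_ <- matrix(0, PZ, PX); pk <- matrix(0, PZ, PX)
  if (is.complex(img)) pi_ <- matrix(complex(real = 0), PZ, PX)
  pi_[seq_len(Z), seq_len(X)] <- img
  pk[seq_len(kz), seq_len(kx)] <- kern
  full <- stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE) / (PZ * PX)
  out <- full[hz + seq_len(Z), hx + seq_len(X)]
  if (!is.complex(img) && !is.complex(kern)) out <- Re(out)
  out
}

# Smooth zero-mean random field via separable Gaussian smoothing of white
# noise (mirror-padded), normalized to unit standard deviation.
smooth_field <- function(Z, X, smoothness = 6L) {
  f <- matrix(stats::rnorm(Z * X), Z, X)
  k <- stats::dnorm(seq(-2, 2, length.out = 2L * smoothness + 1L))
  k <- matrix(k / sum(k), ncol = 1)
  f <- conv2_same(f, k)
  f <- conv2_same(f, t(k))
  f / stats::sd(f)
}

# Accumulate bilinear subpixel impulses for one frame onto a Z x X grid.
# Positions are in fractional 0-based pixels; entries outside the grid are
# dropped and counted.
deposit_impulses <- function(fz, fx, amp, Z, X) {
  inside <- fz >= 0 & fz <= Z - 1 & fx >= 0 & fx <= X - 1
  dropped <- sum(!inside)
  fz <- fz[inside]; fx <- fx[inside]; amp <- amp[inside]
  img <- matrix(if (is.complex(amp)) complex(real = 0) else 0, Z, X)
  if (length(fz) == 0L) return(list(img = img, dropped = dropped))
  iz <- floor(fz); ix <- floor(fx)
  wz <- fz - iz; wx <- fx - ix
  idx <- c(); val <- c()
  for (dz in 0:1) for (dx in 0:1) {
    w <- (if (dz == 0) 1 - wz else wz) * (if (dx == 0) 1 - wx else wx)
    keep <- w > 0
    if (!any(keep)) next
    rows <- iz[keep] + dz + 1L
    cols <- ix[keep] + dx + 1L
    idx <- c(idx, (cols - 1L) * Z + rows)
    val <- c(val, amp[keep] * w[keep])
  }
  if (is.complex(val)) {
    re <- rowsum(Re(val), idx); im <- rowsum(Im(val), idx)
    img[as.integer(rownames(re))] <- complex(real = re[, 1], imaginary = im[, 1])
  } else {
    acc <- rowsum(val, idx)
    img[as.integer(rownames(acc))] <- acc[, 1]
  }
  list(img = img, dropped = dropped)
}

#' Synthesize a spatiotemporal ultrasound block
#'
#' Realizes the linear scattering model: every alive scatterer deposits
#' `amplitude x PSF` at its subpixel position (bilinear splitting over the
#' four neighboring pixel centers, realized as impulse deposition followed
#' by convolution with the PSF kernel), a quasi-static tissue clutter field
#' is added, and i.i.d. Gaussian electronic noise is added. Scatterers
#' outside the grid are skipped and counted in `dropped_scatterers`, never
#' an error.
#'
#' The clutter is `clutter_amplitude * (F1 + g(t) * F2)` with two fixed
#' smooth random fields and a slow random-walk gain `g(t)` (standard
#' deviation `clutter_walk_sd` per frame), i.e. a tissue subspace of rank at
#' most 2 in the Casorati matrix; `clutter_walk_sd = 0` gives exactly
#' rank 1.
#'
#' Coordinates: `z` axial increasing downward (rows), `x` lateral increasing
#' rightward (columns), pixel-centered 0-based grid, positions in mm.
#'
#' @param traj a [sample_trajectories()] result.
#' @param psf a [make_gaussian_psf()] result (its pitch defines the grid).
#' @param grid_dim integer length-2 `(Z, X)` pixel counts.
#' @param clutter_amplitude clutter field scale relative to scatterer
#'   amplitudes (0 disables clutter).
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed integer seed for clutter, gain walk and noise.
#' @param clutter_walk_sd per-frame standard deviation of the clutter gain
#'   random walk.
#' @param complex_data if `TRUE`, scatterers carry a fixed random phase and
#'   the block is complex (in-phase/quadrature-like); default magnitude-only.
#' @return an `st_block` (kind `"raw"`) with `data` of dimension
#'   `Z x X x T`.
#' @export
synthesize_block <- function(traj, psf, grid_dim,
                             clutter_amplitude = 0,
                             noise_sigma = 0,
                             seed = 1L,
                             clutter_walk_sd = 0.02,
                             complex_data = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(psf, "psf"))
  if (noise_sigma < 0) stop_invalid("`noise_sigma` must be >= 0")
  Z <- as.integer(grid_dim[1]); X <- as.integer(grid_dim[2])
  Tn <- dim(traj$positions)[2]
  n <- dim(traj$positions)[1]
  pitch <- psf$pixel_pitch
  dropped <- 0L
  blk <- array(if (complex_data) complex(real = 0) else 0, c(Z, X, Tn))

  with_seed(seed, {
    phase <- if (complex_data && n > 0L) stats::runif(n, 0, 2 * pi) else NULL
    if (n > 0L) {
      for (t in seq_len(Tn)) {
        alive <- traj$alive_mask[, t]
        if (!any(alive)) next
        amp <- traj$amplitudes[alive]
        if (complex_data) amp <- amp * exp(1i * phase[alive])
        dep <- deposit_impulses(traj$positions[alive, t, 2] / pitch,
                                traj$positions[alive, t, 1] / pitch,
                                amp, Z, X)
        dropped <- dropped + dep$dropped
        if (any(dep$img != 0)) blk[, , t] <- conv2_same(dep$img, psf$kernel)
      }
    }
    if (clutter_amplitude > 0) {
      f1 <- smooth_field(Z, X)
      f2 <- smooth_field(Z, X)
      g <- cumsum(stats::rnorm(Tn, 0, clutter_walk_sd))
      for (t in seq_len(Tn)) {
        blk[, , t] <- blk[, , t] + clutter_amplitude * (f1 + g[t] * f2)
      }
    }
    if (noise_sigma > 0) {
      if (complex_data) {
        blk <- blk + array(complex(real = stats::rnorm(Z * X * Tn, 0, noise_sigma),
                                   imaginary = stats::rnorm(Z * X * Tn, 0, noise_sigma)),
                           c(Z, X, Tn))
      } else {
        blk <- blk + array(stats::rnorm(Z * X * Tn, 0, noise_sigma), c(Z, X, Tn))
      }
    }
  })
  out <- new_st_block(blk, pitch, 1 / traj$frame_interval, kind = "raw")
  out$dropped_scatterers <- dropped
  if (dropped > 0L) {
    message(sprintf("synthesize_block: %d scatterer-frame positions outside the grid were skipped", dropped))
  }
  out
}

#' Total energy of a block
#' @param block an `st_block`.
#' @return sum of squared magnitudes.
#' @export
block_energy <- function(block) {
  sum(Mod(block$data)^2)
}
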