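# Doppler-domain processing: SVD clutter filtering on the Casorati matrix,
# power Doppler accumulation, slow-time spectral flow separation (used for
# training-set augmentation), temporal truncation/interpolation, and
# sliding-window Doppler series.

#' SVD clutter filter specification
#'
#' @param low_cutoff `k`, number of leading singular components removed
#'   (tissue clutter), or `"adaptive"` to place the cutoff at the knee of
#'   the singular-value curve.
#' @param high_cutoff optional number of trailing components removed
#'   (noise), default 0.
#' @return object of class `svd_filter_spec`.
#' @export
svd_filter_spec <- function(low_cutoff = 2L, high_cutoff = 0L) {
  if (!identical(low_cutoff, "adaptive")) {
    if (low_cutoff < 0) stop_invalid("`low_cutoff` must be >= 0")
  }
  if (high_cutoff < 0) stop_invalid("`high_cutoff` must be >= 0")
  structure(list(low_cutoff = low_cutoff, high_cutoff = high_cutoff),
            class = "svd_filter_spec")
}

# Knee of the log singular-value curve: point of maximum distance to the
# chord joining the endpoints.
svd_knee <- function(sv) {
  y <- log(pmax(sv, .Machine$double.eps))
  n <- length(y)
  x <- seq_len(n)
  chord <- y[1] + (y[n] - y[1]) * (x - 1) / (n - 1)
  which.max(chord - y) - 1L
}

#' SVD clutter filter
#'
#' Forms the Casorati matrix (`Z*X x T`), zeroes the `k` leading singular
#' components (quasi-static tissue) and optionally a trailing noise band,
#' and reshapes back. Output energy never exceeds input energy.
#'
#' @param block a raw `st_block`.
#' @param spec an [svd_filter_spec()].
#' @return filtered `st_block` with `kind = "clutter_filtered"` and an
#'   attached `singular_values` field.
#' @export
#' @examples
#' # a static (rank-1) block is annihilated by k = 1
svd_clutter_filter <- function(block, spec = svd_filter_spec()) {
  stopifnot(inherits(block, "st_block"))
  if (!identical(block$kind, "raw")) {
    stop_invalid("`block` must have kind 'raw' (got '%s')", block$kind)
  }
  d <- dim(block$data)
  Z <- d[1]; X <- d[2]; Tn <- d[3]
  C <- matrix(block$data, Z * X, Tn)
  rank_bound <- min(Z * X, Tn)
  sv <- svd(C)
  k <- spec$low_cutoff
  if (identical(k, "adaptive")) k <- svd_knee(sv$d)
  k <- as.integer(k)
  if (k >= rank_bound) {
    stop_invalid("low cutoff k = %d must be < min(Z*X, T) = %d", k, rank_bound)
  }
  if (spec$high_cutoff >= rank_bound - k) {
    stop_invalid("high cutoff must be < min(Z*X, T) - k")
  }
  keep <- rep(TRUE, length(sv$d))
  if (k > 0L) keep[seq_len(k)] <- FALSE
  if (spec$high_cutoff > 0L) {
    keep[seq(length(keep) - spec$high_cutoff + 1L, length(keep))] <- FALSE
  }
  Df <- sv$d
  Df[!keep] <- 0
  Cf <- sv$u %*% (Df * Conj(t(sv$v)))
  out <- block
  out$data <- array(Cf, c(Z, X, Tn))
  if (!is.complex(block$data)) out$data <- array(Re(Cf), c(Z, X, Tn))
  out$kind <- "clutter_filtered"
  out$singular_values <- sv$d
  out$svd_cutoff <- k
  out
}

#' Power Doppler reconstruction
#'
#' Per-pixel mean over slow time of the squared signal magnitude. The mean
#' (rather than the sum) keeps images comparable across ensemble lengths.
#'
#' @param block a clutter-filtered `st_block`.
#' @return object of class `power_doppler_image` with `intensity`
#'   (`Z x X`, nonnegative), `pixel_pitch` and `n_frames_used`.
#' @export
power_doppler <- function(block) {
  stopifnot(inherits(block, "st_block"))
  if (!identical(block$kind, "clutter_filtered")) {
    stop_invalid("`block` must be clutter_filtered; run svd_clutter_filter() first")
  }
  d <- dim(block$data)
  if (d[3] < 1L) stop_invalid("block has no frames")
  intensity <- apply(Mod(block$data)^2, c(1, 2), mean)
  structure(list(intensity = intensity, pixel_pitch = block$pixel_pitch,
                 n_frames_used = d[3]),
            class = "power_doppler_image")
}

#' @export
print.power_doppler_image <- function(x, ...) {
  cat(sprintf("Power Doppler image: %d x %d (%d frames), mean intensity %.3g\n",
              nrow(x$intensity), ncol(x$intensity), x$n_frames_used,
              mean(x$intensity)))
  invisible(x)
}

#' Flow-separation augmentation
#'
#' Partitions the slow-time spectrum of a clutter-filtered block into
#' `n_bands` contiguous bands of (nearly) equal width over the signed
#' frequency axis and returns one band-filtered block per band. The bands
#' sum elementwise to the input. For complex data the signed bands are
#' direction-resolved; real-valued data fold negative frequencies, so
#' direction information is lost (each band keeps its conjugate-symmetric
#' counterpart implicitly through the real part).
#'
#' Used as a simplified slow-time spectral partition for training-set
#' augmentation (one augmented sample per band).
#'
#' @param block a clutter-filtered `st_block` with `T >= 2 * n_bands`.
#' @param n_bands number of spectral bands (>= 1).
#' @return list of `n_bands` blocks (same kind/grid as the input).
#' @export
flow_separation_augment <- function(block, n_bands) {
  stopifnot(inherits(block, "st_block"))
  if (!identical(block$kind, "clutter_filtered")) {
    stop_invalid("`block` must be clutter_filtered")
  }
  d <- dim(block$data)
  Tn <- d[3]
  if (n_bands < 1L) stop_invalid("`n_bands` must be >= 1")
  if (n_bands > Tn / 2) stop_invalid("`n_bands` must be <= T/2 = %g", Tn / 2)
  C <- matrix(block$data, d[1] * d[2], Tn)
  S <- t(stats::mvfft(t(C)))                     # spectrum along slow time
  # contiguous bands over the fftshifted (signed) frequency axis
  shift_order <- c(seq(floor(Tn / 2) + 1L, Tn), seq_len(floor(Tn / 2)))
  bounds <- round(seq(0, Tn, length.out = n_bands + 1L))
  out <- vector("list", n_bands)
  cplx <- is.complex(block$data)
  for (b in seq_len(n_bands)) {
    sel_shifted <- seq(bounds[b] + 1L, bounds[b + 1L])
    sel <- shift_order[sel_shifted]
    Sb <- matrix(complex(real = 0), nrow(S), Tn)
    Sb[, sel] <- S[, sel]
    Cb <- t(stats::mvfft(t(Sb), inverse = TRUE)) / Tn
    ob <- block
    ob$data <- array(if (cplx) Cb else Re(Cb), d)
    ob$band <- b
    out[[b]] <- ob
  }
  out
}

#' Temporal truncation followed by linear interpolation
#'
#' Decimates the slow-time axis by `keep_every` (always retaining the final
#' frame so the interpolation spans the whole block) and linearly
#' interpolates back to the original frame count. Emulates feeding a
#' shorter acquisition to a network trained at a fixed ensemble length.
#'
#' @param block an `st_block`.
#' @param keep_every decimation factor (>= 1, < T, with `T/keep_every >= 2`).
#' @return `st_block` with the same dimensions.
#' @export
truncate_and_interpolate <- function(block, keep_every) {
  stopifnot(inherits(block, "st_block"))
  d <- dim(block$data)
  Tn <- d[3]
  keep_every <- as.integer(keep_every)
  if (keep_every < 1L) stop_invalid("`keep_every` must be >= 1")
  if (keep_every >= Tn) stop_invalid("`keep_every` must be < T = %d", Tn)
  if (Tn / keep_every < 2) stop_invalid("T / keep_every must be >= 2")
  if (keep_every == 1L) return(block)
  kept <- sort(unique(c(seq(1L, Tn, by = keep_every), Tn)))
  M <- matrix(block$data, d[1] * d[2], Tn)
  interp_rows <- function(mat) {
    t(apply(mat[, kept, drop = FALSE], 1, function(y)
      stats::approx(kept, y, xout = seq_len(Tn))$y))
  }
  out <- block
  if (is.complex(block$data)) {
    out$data <- array(complex(real = interp_rows(Re(M)),
                              imaginary = interp_rows(Im(M))), d)
  } else {
    out$data <- array(interp_rows(M), d)
  }
  out
}

#' Stretch a short acquisition to a trained ensemble length
#'
#' Keeps the first `n_keep` frames (a genuinely shorter contiguous
#' acquisition at the same frame rate) and linearly interpolates them onto
#' the original `T`-frame grid, so the block can be fed to a model trained
#' at the full ensemble length. This is the harsher — and physically
#' faithful — emulation of a short acquisition; compare
#' [truncate_and_interpolate()], which decimates (emulating a lower frame
#' rate over the same duration).
#'
#' @param block an `st_block`.
#' @param n_keep number of leading frames kept (`2 <= n_keep <= T`).
#' @return `st_block` with the original dimensions.
#' @export
prefix_truncate_interpolate <- function(block, n_keep) {
  stopifnot(inherits(block, "st_block"))
  d <- dim(block$data)
  Tn <- d[3]
  n_keep <- as.integer(n_keep)
  if (n_keep < 2L || n_keep > Tn) stop_invalid("`n_keep` must be in [2, T]")
  if (n_keep == Tn) return(block)
  src <- 1 + (seq_len(Tn) - 1) * (n_keep - 1) / (Tn - 1)
  lo <- pmin(floor(src), n_keep - 1)
  w <- src - lo
  out <- block
  a <- block$data[, , lo, drop = FALSE]
  b <- block$data[, , lo + 1, drop = FALSE]
  warr <- aperm(array(w, c(Tn, d[1], d[2])), c(2, 3, 1))
  out$data <- a * (1 - warr) + b * warr
  out
}

#' Sliding-window reconstruction series
#'
#' Applies a reconstructor to consecutive temporal windows of a block. The
#' number of outputs is `floor((T - window) / step) + 1`.
#'
#' @param block a clutter-filtered `st_block`.
#' @param window window length in frames (`<= T`).
#' @param step window step in frames (>= 1).
#' @param reconstructor `"power_doppler"`, or a fitted [cspd()] model, or a
#'   function taking an `st_block` and returning an image object or matrix.
#' @return list with `images` (list), `start_frames` (1-based window starts)
#'   and `times` (window start times in seconds).
#' @export
sliding_window_series <- function(block, window, step,
                                  reconstructor = "power_doppler") {
  stopifnot(inherits(block, "st_block"))
  d <- dim(block$data)
  Tn <- d[3]
  if (window > Tn) stop_invalid("`window` (%d) must be <= T (%d)", window, Tn)
  if (step < 1L) stop_invalid("`step` must be >= 1")
  recon <- reconstructor
  if (identical(reconstructor, "power_doppler")) recon <- power_doppler
  if (inherits(reconstructor, "cspd")) {
    recon <- function(b) stats::predict(reconstructor, b)
  }
  starts <- seq(1L, Tn - window + 1L, by = step)
  images <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    sub <- block
    sub$data <- block$data[, , starts[i] + seq_len(window) - 1L, drop = FALSE]
    images[[i]] <- recon(sub)
  }
  list(images = images, start_frames = starts,
       times = (starts - 1L) / block$frame_rate)
}

#' Log-compress an intensity image for display
#'
#' Display-only decibel compression; all quantitative metrics operate on
#' the linear scale.
#'
#' @param intensity nonnegative matrix.
#' @param dynamic_range dB span retained below the maximum (default 70).
#' @return matrix in `[0, 1]` (0 at/below `-dynamic_range` dB, 1 at peak).
#' @export
log_compress <- function(intensity, dynamic_range = 70) {
  m <- max(intensity)
  if (m <= 0) return(intensity * 0)
  db <- 10 * log10(pmax(intensity / m, 10^(-dynamic_range / 10 - 2)))
  pmin(pmax(1 + db / dynamic_range, 0), 1)
}
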