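# Ultrasound localization microscopy: localize sparse strong scatterers
# (microbubble-like) frame by frame, then accumulate their subpixel
# positions on an upsampled grid. The accumulated map is the super-resolved
# training target for the learned reconstruction.

#' Localize scatterers in a single frame
#'
#' Matched-filter localization: the frame is cross-correlated with the PSF
#' kernel; regional maxima (8-neighborhood) of the correlation map whose
#' raw amplitude exceeds `detection_threshold` times the frame maximum (and
#' an optional absolute floor), and whose energy-normalized correlation
#' (normalized cross-correlation score) exceeds `min_ncc`, are retained.
#' Each detection is refined to subpixel precision by an intensity-weighted
#' centroid over a window of PSF-FWHM extent with local background
#' subtraction. (Maxima are sought on the matched-filter output rather than
#' on the normalized score: for an isolated scatterer the normalized score
#' is near-constant around the peak, so its local maxima are uninformative,
#' while it remains a good acceptance gate against non-PSF-shaped spikes.)
#'
#' @param frame `Z x X` nonnegative matrix (one slow-time frame, magnitude).
#' @param psf a [make_gaussian_psf()] result.
#' @param detection_threshold fraction of the frame maximum in (0, 1).
#' @param min_amplitude absolute amplitude floor for detections (useful to
#'   reject noise-only frames; default 0).
#' @param min_ncc normalized cross-correlation acceptance floor.
#' @return data.frame with columns `x`, `z` (mm) and `amplitude`; empty on
#'   blank frames.
#' @export
localize_frame <- function(frame, psf, detection_threshold = 0.2,
                           min_amplitude = 0, min_ncc = 0.5) {
  stopifnot(is.matrix(frame), inherits(psf, "psf"))
  if (detection_threshold <= 0 || detection_threshold >= 1) {
    stop_invalid("`detection_threshold` must be in (0, 1)")
  }
  empty <- data.frame(x = numeric(0), z = numeric(0), amplitude = numeric(0))
  fmax <- max(frame)
  if (!is.finite(fmax) || fmax <= 0 || fmax < min_amplitude) return(empty)
  kern <- psf$kernel
  corr <- conv2_same(frame, kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern))), drop = FALSE])
  le <- conv2_same(frame^2, matrix(1, nrow(kern), ncol(kern)))
  ncc <- corr / sqrt(pmax(le, max(le) * 1e-9))
  Z <- nrow(frame); X <- ncol(frame)
  # regional maxima on the interior of the matched-filter map; exact ties
  # (e.g. a scatterer at a half-pixel position) resolve to the first pixel
  # in raster order
  ctr <- corr[2:(Z - 1), 2:(X - 1)]
  is_max <- TRUE
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    nb <- corr[2:(Z - 1) + dz, 2:(X - 1) + dx]
    is_max <- is_max & if (dz < 0 || (dz == 0 && dx < 0)) ctr > nb else ctr >= nb
  }
  amp_ok <- frame[2:(Z - 1), 2:(X - 1)] >= pmax(detection_threshold * fmax,
                                                min_amplitude)
  ncc_ok <- ncc[2:(Z - 1), 2:(X - 1)] >= min_ncc
  pk <- which(is_max & amp_ok & ncc_ok, arr.ind = TRUE)
  if (nrow(pk) == 0L) return(empty)
  pk <- pk + 1L  # back to full-frame indices
  wz <- max(1L, ceiling(psf$fwhm_mm["axial"] / psf$pixel_pitch))
  wx <- max(1L, ceiling(psf$fwhm_mm["lateral"] / psf$pixel_pitch))
  out <- matrix(NA_real_, nrow(pk), 3L)
  for (i in seq_len(nrow(pk))) {
    rz <- max(1L, pk[i, 1] - wz):min(Z, pk[i, 1] + wz)
    rx <- max(1L, pk[i, 2] - wx):min(X, pk[i, 2] + wx)
    patch <- frame[rz, rx, drop = FALSE]
    patch <- patch - min(patch)
    s <- sum(patch)
    if (s <= 0) next
    cz <- sum(patch * (rz - 1L)) / s       # 0-based pixel coordinates
    cx <- sum(t(patch) * (rx - 1L)) / s
    out[i, ] <- c(cx * psf$pixel_pitch, cz * psf$pixel_pitch, frame[pk[i, 1], pk[i, 2]])
  }
  out <- out[stats::complete.cases(out), , drop = FALSE]
  data.frame(x = out[, 1], z = out[, 2], amplitude = out[, 3])
}

#' Localize every frame of a block
#'
#' @param block a clutter-filtered `st_block` (magnitude is taken).
#' @param psf the imaging PSF.
#' @param detection_threshold,min_amplitude see [localize_frame()].
#' @return object of class `localization_set`: data.frame `events` with
#'   columns `frame`, `x`, `z`, `amplitude`, plus grid metadata.
#' @export
localize_block <- function(block, psf, detection_threshold = 0.2,
                           min_amplitude = 0) {
  stopifnot(inherits(block, "st_block"))
  d <- dim(block$data)
  evs <- vector("list", d[3])
  for (t in seq_len(d[3])) {
    loc <- localize_frame(Mod(block$data[, , t]), psf,
                          detection_threshold, min_amplitude)
    if (nrow(loc) > 0L) {
      loc$frame <- t
      evs[[t]] <- loc
    }
  }
  events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(x = numeric(0), z = numeric(0),
                         amplitude = numeric(0), frame = integer(0))
  }
  structure(list(events = events[, c("frame", "x", "z", "amplitude")],
                 grid_dim = d[1:2], pixel_pitch = block$pixel_pitch),
            class = "localization_set")
}

#' Accumulate localizations into a super-resolved count map
#'
#' Each localization event increments the nearest pixel of an `R`-fold
#' upsampled grid by one (Dirac accumulation). Events outside the grid are
#' dropped and counted. Total retained counts are conserved exactly.
#'
#' @param locs a `localization_set` (or plain data.frame with `x`, `z` mm).
#' @param grid_dim native grid `(Z, X)`.
#' @param R integer upsampling factor (>= 1).
#' @param pixel_pitch native pixel pitch in mm (taken from `locs` when
#'   available).
#' @return object of class `ulm_image`: `counts` (`R*Z x R*X`), `R`,
#'   `pixel_pitch` (fine pitch, mm), `n_events`, `dropped`, and `intensity`
#'   (`NULL` until [normalize_ulm()] is applied).
#' @export
accumulate_ulm <- function(locs, grid_dim = NULL, R = 4L, pixel_pitch = NULL) {
  if (inherits(locs, "localization_set")) {
    grid_dim <- grid_dim %||% locs$grid_dim
    pixel_pitch <- pixel_pitch %||% locs$pixel_pitch
    ev <- locs$events
  } else {
    ev <- locs
  }
  R <- as.integer(R)
  if (R < 1L) stop_invalid("`R` must be a positive integer")
  if (is.null(grid_dim) || is.null(pixel_pitch)) {
    stop_invalid("`grid_dim` and `pixel_pitch` are required")
  }
  fz <- grid_dim[1] * R; fx <- grid_dim[2] * R
  fine <- pixel_pitch / R
  counts <- matrix(0, fz, fx)
  dropped <- 0L
  if (nrow(ev) > 0L) {
    iz <- round(ev$z / fine) + 1L
    ix <- round(ev$x / fine) + 1L
    ok <- iz >= 1L & iz <= fz & ix >= 1L & ix <= fx
    dropped <- sum(!ok)
    if (any(ok)) {
      acc <- rowsum(rep(1, sum(ok)), (ix[ok] - 1L) * fz + iz[ok])
      counts[as.integer(rownames(acc))] <- acc[, 1]
    }
  }
  if (dropped > 0L) {
    message(sprintf("accumulate_ulm: %d events outside the grid were dropped", dropped))
  }
  structure(list(counts = counts, R = R, pixel_pitch = fine,
                 native_grid = as.integer(grid_dim),
                 n_events = as.integer(nrow(ev)) - dropped, dropped = dropped,
                 intensity = NULL),
            class = "ulm_image")
}

#' @export
print.ulm_image <- function(x, ...) {
  cat(sprintf("ULM image: %d x %d (R = %d, %.1f um pitch), %d events\n",
              nrow(x$counts), ncol(x$counts), x$R, 1e3 * x$pixel_pitch,
              x$n_events))
  invisible(x)
}

#' Normalize a ULM count map for training
#'
#' Saturates counts at the given quantile of the nonzero counts and scales
#' to `[0, 1]`, filling the `intensity` field.
#'
#' @param ulm a `ulm_image`.
#' @param saturation_quantile quantile of nonzero counts at which to
#'   saturate (default 0.99).
#' @return the `ulm_image` with `intensity` set.
#' @export
normalize_ulm <- function(ulm, saturation_quantile = 0.99) {
  stopifnot(inherits(ulm, "ulm_image"))
  nz <- ulm$counts[ulm$counts > 0]
  if (length(nz) == 0L) {
    ulm$intensity <- ulm$counts
    return(ulm)
  }
  cap <- stats::quantile(nz, saturation_quantile, names = FALSE)
  if (cap <= 0) cap <- max(nz)
  ulm$intensity <- pmin(ulm$counts, cap) / cap
  ulm
}

#' Configuration for a simulated training pair
#'
#' Bundles the acquisition/reconstruction conditions for one imaging plane.
#' Defaults reflect the fixture scale used throughout the package tests
#' (64 x 64 grid at 12.5 um pitch, 20 MHz-regime PSF, 1000 Hz frame rate).
#'
#' @param grid_dim native grid `(Z, X)`.
#' @param pixel_pitch native pitch in mm.
#' @param wavelength,f_number PSF parameters (mm / dimensionless).
#' @param frame_rate slow-time frame rate in Hz.
#' @param n_blocks number of input blocks per plane.
#' @param block_frames frames per input block.
#' @param ulm_frames total frames synthesized for the ULM target.
#' @param ulm_chunk frames per ULM synthesis/filter chunk.
#' @param R super-resolution upsampling factor.
#' @param contrast_free_fraction fraction of input blocks synthesized in the
#'   dense/weak contrast-free regime (the rest are sparse/strong
#'   contrast-enhanced), at least one of each when `n_blocks >= 2`.
#' @param clutter_amplitude,noise_sigma forward-model nuisance levels.
#' @param svd_cutoff leading singular components removed by the clutter
#'   filter.
#' @param detection_threshold ULM detection threshold (fraction of frame
#'   max).
#' @param pulsatility a [pulsatility_profile()].
#' @return list of class `training_pair_config`.
#' @export
training_pair_config <- function(grid_dim = c(64L, 64L),
                                 pixel_pitch = 0.0125,
                                 wavelength = 0.077,
                                 f_number = 1,
                                 frame_rate = 1000,
                                 n_blocks = 3L,
                                 block_frames = 16L,
                                 ulm_frames = 1500L,
                                 ulm_chunk = 250L,
                                 R = 4L,
                                 contrast_free_fraction = 0.1,
                                 clutter_amplitude = 40,
                                 noise_sigma = 0.3,
                                 svd_cutoff = 2L,
                                 detection_threshold = 0.25,
                                 pulsatility = pulsatility_profile(0)) {
  if (ulm_frames < block_frames) {
    stop_invalid("`ulm_frames` (%d) must be >= `block_frames` (%d)",
                 ulm_frames, block_frames)
  }
  structure(as.list(environment()), class = "training_pair_config")
}

#' Simulate one imaging plane: input blocks plus ULM target
#'
#' Emits `n_blocks` clutter-filtered spatiotemporal input blocks (a mix of
#' contrast-free and contrast-enhanced regimes) and one ULM target built
#' from a much longer contrast-enhanced synthesis of the same vessel tree
#' (localize every frame, accumulate, saturate and scale to `[0, 1]`).
#'
#' @param tree a [make_vessel_tree()] result.
#' @param config a [training_pair_config()].
#' @param seed integer seed; child seeds are split per block/chunk.
#' @return list with `blocks` (list of `st_block`), `ulm` (`ulm_image` with
#'   `intensity` set), `psf`, `tree`, `config`, `seed`.
#' @export
make_training_pair <- function(tree, config = training_pair_config(),
                               seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"),
            inherits(config, "training_pair_config"))
  cfg <- config
  psf <- make_gaussian_psf(cfg$wavelength, cfg$f_number, cfg$pixel_pitch)
  dt <- 1 / cfg$frame_rate
  spec <- svd_filter_spec(cfg$svd_cutoff)

  n_cf <- if (cfg$n_blocks >= 2L) {
    max(1L, round(cfg$contrast_free_fraction * cfg$n_blocks))
  } else if (cfg$contrast_free_fraction >= 0.5) 1L else 0L
  regimes <- c(rep("contrast_free", n_cf),
               rep("contrast_enhanced", cfg$n_blocks - n_cf))

  # each acquisition starts at an arbitrary (seed-derived) cardiac phase
  rand_phase <- function(s) (s %% 9973L) / 9973
  blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    rg <- regime_defaults(regimes[b])
    tr <- sample_trajectories(tree, density = rg$density,
                              n_frames = cfg$block_frames,
                              frame_interval = dt,
                              pulsatility = cfg$pulsatility,
                              cardiac_phase = rand_phase(child_seed(seed, 1L, b)),
                              seed = child_seed(seed, 1L, b),
                              amplitude_scale = rg$amplitude_scale)
    raw <- synthesize_block(tr, psf, cfg$grid_dim,
                            clutter_amplitude = cfg$clutter_amplitude,
                            noise_sigma = cfg$noise_sigma,
                            seed = child_seed(seed, 2L, b))
    blk <- svd_clutter_filter(raw, spec)
    blk$regime <- regimes[b]
    blocks[[b]] <- blk
  }

  rg <- regime_defaults("contrast_enhanced")
  n_chunks <- ceiling(cfg$ulm_frames / cfg$ulm_chunk)
  all_events <- vector("list", n_chunks)
  min_amp <- 6 * cfg$noise_sigma
  for (ch in seq_len(n_chunks)) {
    nf <- min(cfg$ulm_chunk, cfg$ulm_frames - (ch - 1L) * cfg$ulm_chunk)
    tr <- sample_trajectories(tree, density = rg$density, n_frames = nf,
                              frame_interval = dt,
                              pulsatility = cfg$pulsatility,
                              cardiac_phase = rand_phase(child_seed(seed, 3L, ch)),
                              seed = child_seed(seed, 3L, ch),
                              amplitude_scale = rg$amplitude_scale)
    raw <- synthesize_block(tr, psf, cfg$grid_dim,
                            clutter_amplitude = cfg$clutter_amplitude,
                            noise_sigma = cfg$noise_sigma,
                            seed = child_seed(seed, 4L, ch))
    flt <- svd_clutter_filter(raw, spec)
    locs <- localize_block(flt, psf, cfg$detection_threshold,
                           min_amplitude = min_amp)
    if (nrow(locs$events) > 0L) {
      locs$events$frame <- locs$events$frame + (ch - 1L) * cfg$ulm_chunk
      all_events[[ch]] <- locs$events
    }
  }
  events <- do.call(rbind, all_events[!vapply(all_events, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(frame = integer(0), x = numeric(0), z = numeric(0),
                         amplitude = numeric(0))
  }
  locs <- structure(list(events = events, grid_dim = cfg$grid_dim,
                         pixel_pitch = cfg$pixel_pitch),
                    class = "localization_set")
  ulm <- normalize_ulm(accumulate_ulm(locs, cfg$grid_dim, cfg$R,
                                      cfg$pixel_pitch))
  list(blocks = blocks, ulm = ulm, psf = psf, tree = tree,
       config = cfg, seed = seed, localizations = locs)
}
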