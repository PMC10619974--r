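# Scatterer trajectory sampling: red-blood-cell-like or microbubble-like
# scatterers advected along vessel centerlines at the local mean speed,
# modulated by the cardiac pulsatility profile. Trajectories are the
# simulator's latent truth against which localization and Doppler
# reconstructions are judged.

#' Sample scatterer trajectories along a vessel tree
#'
#' Seeds scatterers along every vessel segment at a mean linear density
#' (Poisson count per segment) and advects them along the centerline at the
#' segment's mean speed times the instantaneous pulsatility scale. Each
#' scatterer keeps a fixed perpendicular offset within the lumen. A
#' scatterer reaching the end of its segment is recycled at the segment
#' entrance; it is marked dead (`alive_mask` FALSE) for the transit frame so
#' downstream consumers can ignore the wrap discontinuity. The number of
#' scatterers is therefore approximately constant over time.
#'
#' Amplitudes model scatterer echogenicity: log-normal with unit median,
#' scaled by `amplitude_scale`. A dense/weak setting emulates contrast-free
#' red-blood-cell speckle; a sparse/strong setting emulates injected
#' microbubbles (see [regime_defaults()]).
#'
#' @param tree a [make_vessel_tree()] result.
#' @param density mean scatterer count per mm of vessel length (>= 0).
#' @param n_frames number of slow-time frames (>= 1).
#' @param frame_interval slow-time sampling interval in seconds.
#' @param pulsatility a [pulsatility_profile()]; default no modulation.
#' @param cardiac_phase starting cardiac phase in `[0, 1)` (acquisitions
#'   begin at arbitrary points of the cardiac cycle).
#' @param seed integer seed; output is bitwise reproducible per seed.
#' @param amplitude_scale echogenicity multiplier.
#' @param amplitude_sdlog log-sd of the per-scatterer log-normal amplitude.
#' @return object of class `trajectory_set` with `positions`
#'   (n x T x 2 array, mm; columns x then z), `amplitudes` (n),
#'   `alive_mask` (n x T logical), `frame_interval`, `segment_id` (n),
#'   `segment_speed` (n) and the generating `seed`.
#' @export
#' @examples
#' tr <- make_vessel_tree(seed = 1, n_roots = 1, branching_depth = 0,
#'                        parallel_pair = FALSE)
#' ts <- sample_trajectories(tr, density = 20, n_frames = 10,
#'                           frame_interval = 1e-3, seed = 2)
#' dim(ts$positions)
sample_trajectories <- function(tree, density, n_frames, frame_interval = 1e-3,
                                pulsatility = pulsatility_profile(0),
                                cardiac_phase = 0,
                                seed = 1L,
                                amplitude_scale = 1,
                                amplitude_sdlog = 0.3) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (density < 0) stop_invalid("`density` must be >= 0, got %g", density)
  if (n_frames < 1) stop_invalid("`n_frames` must be >= 1")
  tt <- (seq_len(n_frames) - 1) * frame_interval +
    cardiac_phase * pulsatility$cardiac_period
  scale_t <- pulsatility_scale(pulsatility, tt)

  pos_list <- list(); amp_list <- list(); alive_list <- list()
  seg_id <- integer(0); seg_speed <- numeric(0)
  with_seed(seed, {
    for (si in seq_along(tree$segments)) {
      seg <- tree$segments[[si]]
      L <- polyline_length(seg$points)
      if (L <= 0) next
      n_s <- stats::rpois(1L, density * L)
      if (n_s == 0L) next
      s0 <- stats::runif(n_s, 0, L)
      off <- stats::runif(n_s, -1, 1) * seg$radius
      amp <- stats::rlnorm(n_s, 0, amplitude_sdlog) * amplitude_scale
      # cumulative arc-length travelled (same for all scatterers of the
      # segment: speed depends on the segment and the cardiac phase only)
      disp <- c(0, cumsum(seg$mean_speed * scale_t[-n_frames] * frame_interval))
      s_all <- outer(s0, disp, "+")            # n_s x T
      laps <- floor(s_all / L)
      alive <- cbind(TRUE, laps[, -1, drop = FALSE] == laps[, -n_frames, drop = FALSE])
      s_mod <- s_all %% L
      ctr <- polyline_interp(seg$points, as.vector(s_mod))
      tang <- polyline_tangent(seg$points, as.vector(s_mod))
      nrm <- cbind(-tang[, 2], tang[, 1])      # unit normal
      p <- ctr + nrm * rep(off, times = n_frames)
      pos <- array(NA_real_, c(n_s, n_frames, 2L))
      pos[, , 1] <- matrix(p[, 1], n_s, n_frames)
      pos[, , 2] <- matrix(p[, 2], n_s, n_frames)
      pos_list[[length(pos_list) + 1L]] <- pos
      amp_list[[length(amp_list) + 1L]] <- amp
      alive_list[[length(alive_list) + 1L]] <- alive
      seg_id <- c(seg_id, rep(si, n_s))
      seg_speed <- c(seg_speed, rep(seg$mean_speed, n_s))
    }
  })
  n_tot <- length(seg_id)
  positions <- array(NA_real_, c(n_tot, n_frames, 2L))
  alive_mask <- matrix(TRUE, n_tot, n_frames)
  amplitudes <- numeric(n_tot)
  at <- 0L
  for (i in seq_along(pos_list)) {
    k <- dim(pos_list[[i]])[1]
    positions[at + seq_len(k), , ] <- pos_list[[i]]
    alive_mask[at + seq_len(k), ] <- alive_list[[i]]
    amplitudes[at + seq_len(k)] <- amp_list[[i]]
    at <- at + k
  }
  structure(list(positions = positions, amplitudes = amplitudes,
                 alive_mask = alive_mask, frame_interval = frame_interval,
                 segment_id = seg_id, segment_speed = seg_speed,
                 pulsatility = pulsatility, seed = seed),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d scatterers x %d frames (dt = %g s)\n",
              dim(x$positions)[1], dim(x$positions)[2], x$frame_interval))
  invisible(x)
}

#' Preset scatterer regimes
#'
#' Density/amplitude presets for the two scatterer populations used in
#' mixed training: `contrast_free` emulates dense, weakly echogenic red
#' blood cells; `contrast_enhanced` emulates sparse, strongly echogenic
#' microbubbles suitable for localization.
#'
#' @param regime `"contrast_free"` or `"contrast_enhanced"`.
#' @return list with `density` (per mm) and `amplitude_scale`.
#' @export
regime_defaults <- function(regime = c("contrast_free", "contrast_enhanced")) {
  regime <- match.arg(regime)
  switch(regime,
         contrast_free = list(density = 60, amplitude_scale = 1),
         contrast_enhanced = list(density = 3, amplitude_scale = 25))
}

#' Combine two trajectory sets
#'
#' Concatenates scatterer populations (used by the linearity checks of the
#' forward model and to mix regimes).
#'
#' @param a,b `trajectory_set` objects with identical frame grids.
#' @return merged `trajectory_set`.
#' @export
merge_trajectories <- function(a, b) {
  stopifnot(inherits(a, "trajectory_set"), inherits(b, "trajectory_set"),
            dim(a$positions)[2] == dim(b$positions)[2],
            a$frame_interval == b$frame_interval)
  n <- dim(a$positions)[1] + dim(b$positions)[1]
  Tn <- dim(a$positions)[2]
  positions <- array(NA_real_, c(n, Tn, 2L))
  positions[seq_len(dim(a$positions)[1]), , ] <- a$positions
  positions[dim(a$positions)[1] + seq_len(dim(b$positions)[1]), , ] <- b$positions
  structure(list(positions = positions,
                 amplitudes = c(a$amplitudes, b$amplitudes),
                 alive_mask = rbind(a$alive_mask, b$alive_mask),
                 frame_interval = a$frame_interval,
                 segment_id = c(a$segment_id, b$segment_id),
                 segment_speed = c(a$segment_speed, b$segment_speed),
                 pulsatility = a$pulsatility, seed = NA_integer_),
            class = "trajectory_set")
}
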