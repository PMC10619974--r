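# Synthetic microvasculature: random branching vessel trees with smoothed
# centerlines, and cardiac-cycle pulsatility profiles. These stand in for
# the in vivo microvasculature (e.g., mouse-brain cortical vessels) that
# contrast-free Doppler imaging targets.

#' Cardiac pulsatility profile
#'
#' Periodic unit-mean modulation of blood speed over the cardiac cycle. The
#' default waveform is a rectified-sine systolic peak over a flat diastole:
#' `s(p) = (1 - m) + m * b(p)` where `b` is the unit-mean rectified pulse and
#' `p` the cardiac phase in `[0, 1)`. The instantaneous scale is strictly
#' positive for modulation depth `m < 1` and averages to 1 over a cycle, so
#' the mean speed of a vessel is unchanged by pulsatility.
#'
#' @param modulation_depth `m`, dimensionless in `[0, 1)`. `0` disables
#'   pulsatility.
#' @param cardiac_period cardiac cycle length in seconds (default 0.2 s,
#'   a murine heart rate of 300 bpm).
#' @param base_speed_scale overall dimensionless speed multiplier.
#' @param systole_fraction fraction of the cycle occupied by the systolic
#'   peak.
#' @param n_samples number of stored waveform samples per cycle.
#' @return object of class `pulsatility_profile` with fields
#'   `base_speed_scale`, `modulation_depth`, `cardiac_period`, `waveform`
#'   (unit-mean samples over one cycle) and `phase` (sample phases).
#' @export
#' @examples
#' p <- pulsatility_profile(modulation_depth = 0.5)
#' mean(p$waveform)  # 1
pulsatility_profile <- function(modulation_depth = 0,
                                cardiac_period = 0.2,
                                base_speed_scale = 1,
                                systole_fraction = 0.35,
                                n_samples = 256L) {
  if (modulation_depth < 0 || modulation_depth >= 1) {
    stop_invalid("`modulation_depth` must be in [0, 1), got %g", modulation_depth)
  }
  if (cardiac_period <= 0) stop_invalid("`cardiac_period` must be > 0")
  phase <- (seq_len(n_samples) - 1) / n_samples
  raw <- ifelse(phase < systole_fraction,
                sin(pi * phase / systole_fraction)^2, 0)
  b <- raw / mean(raw)
  waveform <- (1 - modulation_depth) + modulation_depth * b
  waveform <- waveform / mean(waveform)  # exact unit mean on the samples
  structure(list(base_speed_scale = base_speed_scale,
                 modulation_depth = modulation_depth,
                 cardiac_period = cardiac_period,
                 systole_fraction = systole_fraction,
                 waveform = waveform,
                 phase = phase),
            class = "pulsatility_profile")
}

#' Instantaneous speed scale of a pulsatility profile
#'
#' Linear interpolation of the stored periodic waveform at arbitrary times.
#'
#' @param profile a [pulsatility_profile()].
#' @param times numeric vector of times in seconds.
#' @return numeric vector of dimensionless speed scales.
#' @export
pulsatility_scale <- function(profile, times) {
  stopifnot(inherits(profile, "pulsatility_profile"))
  p <- (times / profile$cardiac_period) %% 1
  n <- length(profile$waveform)
  # periodic linear interpolation over the sample grid
  w <- c(profile$waveform, profile$waveform[1])
  ph <- c(profile$phase, 1)
  profile$base_speed_scale * stats::approx(ph, w, xout = p)$y
}

#' @export
print.pulsatility_profile <- function(x, ...) {
  cat(sprintf(
    "Pulsatility profile: depth m = %.2f, period = %.3f s, base scale = %.2f\n",
    x$modulation_depth, x$cardiac_period, x$base_speed_scale))
  invisible(x)
}

new_vessel_segment <- function(points, radius, mean_speed, parent = NA_integer_,
                               tag = "") {
  list(points = points, radius = radius, mean_speed = mean_speed,
       parent = parent, tag = tag)
}

# Correlated random-walk centerline, resampled through a spline for
# smoothness, clipped to the field of view.
grow_centerline <- function(start, heading, fov, margin, step, n_steps,
                            tortuosity) {
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- start
  th <- heading
  k <- 1L
  for (i in seq_len(n_steps)) {
    th <- th + stats::rnorm(1L, 0, tortuosity)
    nxt <- pts[k, ] + step * c(sin(th), cos(th))
    if (nxt[1] < margin || nxt[1] > fov[1] - margin ||
        nxt[2] < margin || nxt[2] > fov[2] - margin) break
    k <- k + 1L
    pts[k, ] <- nxt
  }
  pts <- pts[seq_len(k), , drop = FALSE]
  if (nrow(pts) < 3L) return(pts)
  # spline smoothing on a dense parameter grid
  t0 <- seq_len(nrow(pts))
  tt <- seq(1, nrow(pts), length.out = max(4L * nrow(pts), 16L))
  sm <- cbind(stats::spline(t0, pts[, 1], xout = tt)$y,
              stats::spline(t0, pts[, 2], xout = tt)$y)
  # the spline may overshoot the walk slightly; clamp inside the view
  sm[, 1] <- pmin(pmax(sm[, 1], margin), fov[1] - margin)
  sm[, 2] <- pmin(pmax(sm[, 2], margin), fov[2] - margin)
  sm
}

#' Generate a random branching vessel tree
#'
#' Grows `n_roots` penetrating vessels from the top of the field of view as
#' correlated random walks with spline-smoothed centerlines, each branching
#' into two children per generation with reduced radius and speed. When
#' `branching_depth >= 2` (or `parallel_pair = TRUE`) a pair of straight
#' parallel vessels separated by `pair_separation` is added near the center
#' of the view; at the default separation of half a diffraction-limited
#' point-spread-function width this pair is unresolvable in power Doppler
#' but resolvable in a super-resolved reconstruction, which is what the
#' resolution tests probe.
#'
#' @param seed integer seed; trees are bitwise reproducible per seed.
#' @param field_of_view numeric length-2, lateral and axial extent in mm.
#' @param n_roots number of root vessels (0 gives an empty tree).
#' @param branching_depth generations of binary branching per root.
#' @param root_radius root lumen radius in mm.
#' @param root_speed root mean blood speed in mm/s.
#' @param tortuosity standard deviation (radians) of the heading increments
#'   of the centerline random walk.
#' @param parallel_pair add the sub-diffraction parallel vessel pair
#'   (default: when `branching_depth >= 2`).
#' @param pair_separation center-to-center separation of the pair in mm.
#' @param min_segment_length discard branches shorter than this (mm);
#'   sub-PSF stubs arise only from hitting the view boundary and are not
#'   meaningful vasculature.
#' @return object of class `vessel_tree`: list of segments (each with
#'   `points` (n x 2 matrix, mm), `radius` (mm), `mean_speed` (mm/s),
#'   `parent`, `tag`), plus `field_of_view` and `seed`.
#' @export
#' @examples
#' tr <- make_vessel_tree(seed = 1, field_of_view = c(0.8, 0.8),
#'                        n_roots = 2, branching_depth = 2)
#' length(tr$segments)
make_vessel_tree <- function(seed,
                             field_of_view = c(0.8, 0.8),
                             n_roots = 2L,
                             branching_depth = 2L,
                             root_radius = 0.02,
                             root_speed = 8,
                             tortuosity = 0.25,
                             parallel_pair = branching_depth >= 2L,
                             pair_separation = 0.0385,
                             min_segment_length = 0.12) {
  if (any(field_of_view <= 0)) stop_invalid("`field_of_view` must be positive")
  if (n_roots < 0) stop_invalid("`n_roots` must be >= 0")
  fov <- as.numeric(field_of_view)
  segments <- list()
  with_seed(seed, {
    grow <- function(start, heading, radius, speed, depth, parent) {
      step <- min(fov) / 16
      n_steps <- if (is.na(parent)) 14L else 8L
      pts <- grow_centerline(start, heading, fov, margin = max(radius, 0.02),
                             step = step, n_steps = n_steps,
                             tortuosity = tortuosity)
      if (nrow(pts) < 2L || polyline_length(pts) < min_segment_length) {
        return(invisible(NULL))
      }
      segments[[length(segments) + 1L]] <<-
        new_vessel_segment(pts, radius, speed, parent)
      id <- length(segments)
      if (depth > 0L) {
        endp <- pts[nrow(pts), ]
        tang <- pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]
        th <- atan2(tang[1], tang[2])
        for (sgn in c(-1, 1)) {
          grow(endp, th + sgn * stats::runif(1, 0.3, 0.7),
               radius * stats::runif(1, 0.6, 0.8),
               speed * stats::runif(1, 0.65, 0.85),
               depth - 1L, id)
        }
      }
      invisible(NULL)
    }
    if (n_roots > 0L) {
      for (r in seq_len(n_roots)) {
        x0 <- fov[1] * stats::runif(1, 0.15, 0.85)
        grow(c(x0, 0.03 * fov[2] + 0.02), stats::rnorm(1, 0, 0.15),
             root_radius, root_speed, branching_depth, NA_integer_)
      }
    }
    if (isTRUE(parallel_pair)) {
      zs <- seq(0.15 * fov[2], 0.85 * fov[2], length.out = 24L)
      # random lateral placement: a memorizable fixed position would let a
      # learned reconstruction hallucinate the pair instead of resolving it
      xc <- fov[1] * stats::runif(1, 0.3, 0.7)
      spd <- c(4, 7)  # distinct speeds give the pair distinct slow-time signatures
      for (i in 1:2) {
        xi <- xc + (i - 1.5) * pair_separation
        segments[[length(segments) + 1L]] <- new_vessel_segment(
          cbind(rep(xi, length(zs)), zs), radius = 0.006,
          mean_speed = spd[i], tag = paste0("pair_", letters[i]))
      }
    }
  })
  structure(list(segments = segments, field_of_view = fov, seed = seed),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("Vessel tree: %d segments, FOV %.2f x %.2f mm, total length %.2f mm\n",
              length(x$segments), x$field_of_view[1], x$field_of_view[2],
              vessel_tree_length(x)))
  invisible(x)
}

#' Total centerline length of a vessel tree (mm)
#' @param tree a [make_vessel_tree()] result.
#' @return total length in mm.
#' @export
vessel_tree_length <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (length(tree$segments) == 0L) return(0)
  sum(vapply(tree$segments, function(s) polyline_length(s$points), numeric(1)))
}

#' Rasterize the vessel lumen as a binary mask
#'
#' Auxiliary geometric ground truth: marks every pixel whose center lies
#' within one lumen radius of a vessel centerline, on an `R`-fold
#' super-resolved grid.
#'
#' @param tree a `vessel_tree`.
#' @param grid_dim integer length-2, native grid `(Z, X)`.
#' @param pixel_pitch native pixel pitch in mm.
#' @param R integer upsampling factor.
#' @return `R*Z x R*X` 0/1 matrix.
#' @export
vessel_mask <- function(tree, grid_dim, pixel_pitch, R = 1L) {
  Z <- grid_dim[1] * R; X <- grid_dim[2] * R
  pitch <- pixel_pitch / R
  mask <- matrix(0L, Z, X)
  for (seg in tree$segments) {
    L <- polyline_length(seg$points)
    if (L <= 0) next
    s <- seq(0, L, by = pitch / 2)
    p <- polyline_interp(seg$points, s)
    rad_px <- max(1, ceiling(seg$radius / pitch))
    ix <- round(p[, 1] / pitch); iz <- round(p[, 2] / pitch)
    for (dz in -rad_px:rad_px) for (dx in -rad_px:rad_px) {
      if ((dz * pitch)^2 + (dx * pitch)^2 > seg$radius^2 + 1e-12) next
      zz <- iz + dz + 1L; xx <- ix + dx + 1L
      ok <- zz >= 1L & zz <= Z & xx >= 1L & xx <= X
      mask[cbind(zz[ok], xx[ok])] <- 1L
    }
  }
  mask
}
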