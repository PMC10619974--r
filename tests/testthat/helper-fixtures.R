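# Shared small fixtures built in code.

fixture_psf <- function(pitch = 0.0125) make_gaussian_psf(0.077, 1, pitch)

# hand-built tree: one straight segment, for analytic advection checks
straight_tree <- function(x0 = 0.05, x1 = 0.75, z = 0.4, radius = 0.01,
                          speed = 10, fov = c(0.8, 0.8)) {
  seg <- list(points = cbind(seq(x0, x1, length.out = 32L), z),
              radius = radius, mean_speed = speed, parent = NA_integer_,
              tag = "straight")
  structure(list(segments = list(seg), field_of_view = fov, seed = NA),
            class = "vessel_tree")
}

# tree containing only the sub-diffraction parallel pair
pair_only_tree <- function(separation = 0.0385) {
  make_vessel_tree(seed = 3, field_of_view = c(0.8, 0.8), n_roots = 0,
                   branching_depth = 0, parallel_pair = TRUE,
                   pair_separation = separation)
}

empty_tree <- function() {
  make_vessel_tree(seed = 1, n_roots = 0, branching_depth = 0,
                   parallel_pair = FALSE)
}

# single static scatterer at an arbitrary subpixel position (mm)
static_scatterer <- function(x, z, n_frames = 1L, amplitude = 1) {
  pos <- array(NA_real_, c(1L, n_frames, 2L))
  pos[1, , 1] <- x
  pos[1, , 2] <- z
  structure(list(positions = pos, amplitudes = amplitude,
                 alive_mask = matrix(TRUE, 1L, n_frames),
                 frame_interval = 1e-3, segment_id = 1L,
                 segment_speed = 0, pulsatility = pulsatility_profile(0),
                 seed = NA_integer_),
            class = "trajectory_set")
}

min_dist_to_polyline <- function(pt, points) {
  # dense resampling distance (brute force)
  L <- sum(sqrt(rowSums(diff(points)^2)))
  s <- seq(0, L, length.out = 512L)
  cs <- cumsum(c(0, sqrt(rowSums(diff(points)^2))))
  px <- stats::approx(cs, points[, 1], xout = s)$y
  pz <- stats::approx(cs, points[, 2], xout = s)$y
  min(sqrt((px - pt[1])^2 + (pz - pt[2])^2))
}
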