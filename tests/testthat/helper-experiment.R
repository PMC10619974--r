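# Shared fixture-scale experiment, built lazily and cached across test
# files (simulation and training are the expensive steps; every consumer
# uses the same study conditions).

.fixture_cache <- new.env(parent = emptyenv())

fixture_experiment_config <- function(master_seed = 101L) {
  experiment_config(
    n_planes = 7L,
    n_roots = 2L,
    branching_depth = 2L,
    pair = training_pair_config(grid_dim = c(64L, 64L),
                                pixel_pitch = 0.0125,
                                wavelength = 0.077,
                                f_number = 1,
                                frame_rate = 1000,
                                n_blocks = 3L,
                                block_frames = 64L,
                                ulm_frames = 1500L,
                                ulm_chunk = 250L,
                                R = 4L,
                                pulsatility = pulsatility_profile(0.5, 0.2)),
    augmentation_factor = 4L,
    loss = loss_spec("L1"),
    train = train_config(epochs = 13L, seed = 11L),
    master_seed = master_seed)
}

fixture_generator_spec <- function(in_frames = 64L) {
  generator_spec(in_frames = in_frames, n_levels = 2L, base_channels = 16L,
                 n_extra_upsamples = 2L, seed = 11L)
}

fixture_dataset <- function() {
  if (is.null(.fixture_cache$dataset)) {
    .fixture_cache$dataset <- build_dataset(fixture_experiment_config())
  }
  .fixture_cache$dataset
}

fixture_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    ds <- fixture_dataset()
    .fixture_cache$fit <- cspd(ds$planes[1:6],
                               generator = fixture_generator_spec(),
                               loss = ds$config$loss,
                               config = ds$config$train)
  }
  .fixture_cache$fit
}

fixture_test_plane <- function() {
  fixture_dataset()$planes[[7]]
}

minmax_norm <- function(m) {
  r <- range(m)
  if (r[2] <= r[1]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}
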