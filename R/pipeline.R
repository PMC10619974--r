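# Experiment orchestration: dataset assembly with seed provenance,
# temporal-information ablations, and the sliding-window pulsatility
# analysis. A master seed fans out to per-plane/per-block child seeds via
# child_seed(), so any subset is reproducible in isolation.

#' Experiment configuration
#'
#' Bundles the simulator, dataset and training settings of one experiment.
#' `n_planes` imaging planes are simulated, each with its own vessel tree;
#' the last plane is conventionally held out for testing.
#'
#' @param n_planes number of imaging planes.
#' @param n_roots,branching_depth vessel-tree shape per plane.
#' @param pair a [training_pair_config()].
#' @param augmentation_factor slow-time spectral bands per block used as
#'   augmented training samples (1 disables augmentation).
#' @param loss a [loss_spec()].
#' @param train a [train_config()].
#' @param master_seed master seed for the whole experiment.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n_planes = 7L,
                              n_roots = 2L,
                              branching_depth = 2L,
                              pair = training_pair_config(),
                              augmentation_factor = 1L,
                              loss = loss_spec("L1"),
                              train = train_config(),
                              master_seed = 1L) {
  if (augmentation_factor < 1L) stop_invalid("`augmentation_factor` must be >= 1")
  structure(as.list(environment()), class = "experiment_config")
}

#' Assemble a simulated dataset
#'
#' Simulates every imaging plane (vessel tree, input blocks, ULM target),
#' applies the flow-separation augmentation, and assembles a manifest
#' recording the seed provenance of every artifact and the train/validation
#' assignment (10% of samples, selected under the master seed before any
#' training). With `dir` set, blocks/targets are also written to disk
#' (block containers, ULM TIFF, manifest CSV).
#'
#' @param cfg an [experiment_config()].
#' @param dir optional output directory.
#' @param progress print per-plane progress messages.
#' @return list of class `cspd_dataset`: `planes` (each with `blocks`,
#'   `ulm`, `tree`, `psf`), `manifest` (data.frame), `config`.
#' @export
build_dataset <- function(cfg, dir = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  planes <- vector("list", cfg$n_planes)
  rows <- list()
  for (p in seq_len(cfg$n_planes)) {
    tree_seed <- child_seed(cfg$master_seed, 10L, p)
    pair_seed <- child_seed(cfg$master_seed, 20L, p)
    tree <- make_vessel_tree(seed = tree_seed,
                             field_of_view = cfg$pair$pixel_pitch * cfg$pair$grid_dim,
                             n_roots = cfg$n_roots,
                             branching_depth = cfg$branching_depth)
    pairdat <- make_training_pair(tree, cfg$pair, seed = pair_seed)
    blocks <- pairdat$blocks
    if (cfg$augmentation_factor > 1L) {
      # factor f yields the original block plus f-1 spectral bands, so the
      # training distribution includes the full-spectrum inputs seen at
      # inference time
      aug <- list()
      for (b in seq_along(blocks)) {
        aug[[length(aug) + 1L]] <- blocks[[b]]
        rows[[length(rows) + 1L]] <- data.frame(
          plane = p, block = b, band = NA_integer_,
          regime = blocks[[b]]$regime,
          tree_seed = tree_seed, pair_seed = pair_seed)
        bands <- flow_separation_augment(blocks[[b]],
                                         cfg$augmentation_factor - 1L)
        for (k in seq_along(bands)) {
          bands[[k]]$regime <- blocks[[b]]$regime
          aug[[length(aug) + 1L]] <- bands[[k]]
          rows[[length(rows) + 1L]] <- data.frame(
            plane = p, block = b, band = k,
            regime = blocks[[b]]$regime,
            tree_seed = tree_seed, pair_seed = pair_seed)
        }
      }
      pairdat$blocks <- aug
      pairdat$blocks_raw <- blocks
    } else {
      for (b in seq_along(blocks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          plane = p, block = b, band = NA_integer_,
          regime = blocks[[b]]$regime,
          tree_seed = tree_seed, pair_seed = pair_seed)
      }
    }
    planes[[p]] <- pairdat
    if (progress) message(sprintf("plane %d/%d simulated", p, cfg$n_planes))
  }
  manifest <- do.call(rbind, rows)
  # record the train/validation assignment ahead of training
  n <- nrow(manifest)
  n_val <- max(1L, round(cfg$train$val_fraction * n))
  val_rows <- with_seed(cfg$master_seed, sample.int(n, min(n_val, n - 1L)))
  manifest$split <- "train"
  manifest$split[val_rows] <- "validation"
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(n)
    i <- 0L
    for (p in seq_len(cfg$n_planes)) {
      for (b in seq_along(planes[[p]]$blocks)) {
        i <- i + 1L
        files[i] <- file.path(dir, sprintf("plane%02d_block%03d.rds", p, b))
        write_block(planes[[p]]$blocks[[b]], files[i])
      }
      write_image_tiff(planes[[p]]$ulm,
                       file.path(dir, sprintf("plane%02d_ulm.tiff", p)))
    }
    manifest$file <- files
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(planes = planes, manifest = manifest, config = cfg),
            class = "cspd_dataset")
}

#' @export
print.cspd_dataset <- function(x, ...) {
  cat(sprintf("CS-PD dataset: %d planes, %d samples (%d validation)\n",
              length(x$planes), nrow(x$manifest),
              sum(x$manifest$split == "validation")))
  invisible(x)
}

# truncate a block to its first n frames (raw temporal truncation)
truncate_block <- function(block, n) {
  stopifnot(inherits(block, "st_block"))
  d <- dim(block$data)
  if (n > d[3]) stop_invalid("cannot keep %d of %d frames", n, d[3])
  block$data <- block$data[, , seq_len(n), drop = FALSE]
  block
}

truncate_planes <- function(planes, n) {
  lapply(planes, function(pl) {
    pl$blocks <- lapply(pl$blocks, truncate_block, n = n)
    if (!is.null(pl$blocks_raw)) {
      pl$blocks_raw <- lapply(pl$blocks_raw, truncate_block, n = n)
    }
    pl
  })
}

# held-out evaluation on contrast-free blocks (the contrast-free setting is
# the one the reconstruction exists for, and the one the temporal-information
# ablation probes)
eval_on_plane <- function(fit, plane, transform = identity,
                          regime = "contrast_free") {
  ss <- c(); ps <- c()
  blocks <- plane$blocks_raw %||% plane$blocks
  regimes <- vapply(blocks, function(b) b$regime %||% "", character(1))
  if (any(regimes == regime)) blocks <- blocks[regimes == regime]
  for (blk in blocks) {
    b <- transform(blk)
    img <- stats::predict(fit, b)
    nrm <- function(m) if (max(m) > 0) m / max(m) else m
    ss <- c(ss, ssim(nrm(img$intensity), plane$ulm$intensity))
    ps <- c(ps, psnr(nrm(img$intensity), plane$ulm$intensity))
  }
  c(ssim = mean(ss), psnr = mean(ps))
}

#' Temporal-information ablation
#'
#' Quantifies the value of slow-time information for the learned
#' reconstruction under three protocols: (1) `retrain` — the ensemble
#' length is reduced to each frame count for both training and testing;
#' (2) `truncate_test` — the model is trained at the full ensemble length
#' and the test input is truncated to the frame count and linearly
#' interpolated back; (3) `collapsed` — the input is a single accumulated
#' power Doppler image (no temporal information). SSIM/PSNR against the
#' held-out plane's ULM target are reported per protocol and frame count.
#'
#' @param dataset a [build_dataset()] result.
#' @param frame_counts integer vector of input frame counts (divisors of
#'   the block length).
#' @param test_plane index of the held-out plane (default: last).
#' @param loss,train loss and training configuration (defaults from the
#'   dataset's experiment config).
#' @param full_fit optional model already trained on the full ensemble
#'   length of the training planes (avoids refitting).
#' @param generator optional [generator_spec()] template; `in_frames` is
#'   overridden per protocol.
#' @return data.frame with columns `protocol`, `frames`, `ssim`, `psnr`.
#' @export
run_frame_count_ablation <- function(dataset, frame_counts,
                                     test_plane = length(dataset$planes),
                                     loss = dataset$config$loss,
                                     train = dataset$config$train,
                                     full_fit = NULL, generator = NULL) {
  stopifnot(inherits(dataset, "cspd_dataset"))
  Tfull <- dim(dataset$planes[[1]]$blocks[[1]]$data)[3]
  if (any(frame_counts > Tfull)) {
    stop_invalid("frame counts must be <= block length (%d)", Tfull)
  }
  train_planes <- dataset$planes[-test_plane]
  test <- dataset$planes[[test_plane]]
  rows <- list()

  spec_for <- function(nf) {
    if (is.null(generator)) return(NULL)
    g <- generator
    g$in_frames <- as.integer(nf)
    g
  }
  if (is.null(full_fit)) {
    full_fit <- cspd(train_planes, generator = spec_for(Tfull), loss = loss,
                     config = train)
  }
  for (nf in frame_counts) {
    # matched train/test ensemble length
    fit_n <- if (nf == Tfull) full_fit else {
      cspd(truncate_planes(train_planes, nf), generator = spec_for(nf),
           loss = loss, config = train)
    }
    m <- eval_on_plane(fit_n, truncate_planes(list(test), nf)[[1]])
    rows[[length(rows) + 1L]] <- data.frame(protocol = "retrain", frames = nf,
                                            ssim = m["ssim"], psnr = m["psnr"])
    # truncate-only-at-test: full-length model fed the first nf frames
    # stretched back to the full ensemble length
    m <- eval_on_plane(full_fit, test,
                       transform = function(b) prefix_truncate_interpolate(b, nf))
    rows[[length(rows) + 1L]] <- data.frame(protocol = "truncate_test",
                                            frames = nf,
                                            ssim = m["ssim"], psnr = m["psnr"])
  }
  gc1 <- spec_for(1L)
  fit_c <- cspd(train_planes, generator = gc1, loss = loss, config = train,
                input_mode = "collapsed")
  m <- eval_on_plane(fit_c, test)
  rows[[length(rows) + 1L]] <- data.frame(protocol = "collapsed",
                                          frames = Tfull,
                                          ssim = m["ssim"], psnr = m["psnr"])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window pulsatility analysis
#'
#' Reconstructs a long pulsatile acquisition with a temporal sliding window
#' (power Doppler and, when a model is supplied, CS-PD), extracts the mean
#' intensity over a vessel region of interest per window, and correlates
#' the two series with each other and with the imposed cardiac waveform at
#' the window centers. Without pulsatility both series are flat and the
#' waveform correlation is undefined (`NA`).
#'
#' Each window is clutter-filtered independently (as each short acquisition
#' ensemble would be in practice). The filter removes the clutter
#' components plus a small wall-filter margin of the slowest flow
#' components; this margin is what renders the Doppler series sensitive to
#' the cardiac speed modulation — during diastole more of the (slower,
#' more temporally coherent) flow signal falls into the removed subspace.
#'
#' @param block a long pulsatile `st_block` (raw; a pre-filtered block is
#'   used as-is without per-window filtering).
#' @param pulsatility the [pulsatility_profile()] imposed on the flow.
#' @param model optional fitted [cspd()] model (its `in_frames` must equal
#'   `window`).
#' @param window,step sliding-window length and step in frames.
#' @param roi_native logical matrix on the native grid (vessel ROI) for the
#'   power Doppler series.
#' @param roi_fine logical matrix on the R-grid for the CS-PD series
#'   (default: `roi_native` upsampled).
#' @param svd_cutoff leading singular components removed per window
#'   (clutter rank 2 plus a wall-filter margin of 2 by default).
#' @return list with `times` (window centers, s), `pd_series`,
#'   `cspd_series`, `waveform`, and Pearson correlations `cor_pd_waveform`,
#'   `cor_cspd_waveform`, `cor_pd_cspd`.
#' @export
run_pulsatility_analysis <- function(block, pulsatility, model = NULL,
                                     window = 64L, step = 16L,
                                     roi_native = NULL, roi_fine = NULL,
                                     svd_cutoff = 4L) {
  stopifnot(inherits(block, "st_block"))
  d <- dim(block$data)
  if (is.null(roi_native)) roi_native <- matrix(TRUE, d[1], d[2])
  filt <- if (identical(block$kind, "raw")) {
    spec <- svd_filter_spec(svd_cutoff)
    function(sub) svd_clutter_filter(sub, spec)
  } else {
    identity
  }
  pd_series <- sliding_window_series(block, window, step,
                                     function(sub) power_doppler(filt(sub)))
  pd_vals <- vapply(pd_series$images,
                    function(im) mean(im$intensity[roi_native]), numeric(1))
  centers <- pd_series$times + (window / 2) / block$frame_rate
  # reference: the imposed waveform averaged over each window (a windowed
  # reconstruction can only see the window-mean flow, so the instantaneous
  # waveform is not the apples-to-apples ground truth)
  wf <- vapply(pd_series$start_frames, function(s) {
    mean(pulsatility_scale(pulsatility,
                           (s - 1 + seq_len(window) - 1) / block$frame_rate))
  }, numeric(1))
  cspd_vals <- NULL
  cor_cspd_wf <- NA_real_
  cor_pd_cspd <- NA_real_
  if (!is.null(model)) {
    R <- model$generator$R
    if (is.null(roi_fine)) {
      roi_fine <- upsample_bilinear(roi_native * 1, R) > 0.5
    }
    cs <- sliding_window_series(block, window, step,
                                function(sub) stats::predict(model, filt(sub)))
    # rescale each window's [0,1] image by its ensemble power scale so the
    # series carries the window-to-window intensity modulation
    cspd_vals <- vapply(cs$images,
                        function(im) mean(im$intensity[roi_fine]) *
                          (im$scale %||% 1), numeric(1))
  }
  flat <- function(v) stats::sd(v) < 1e-12
  cor_pd_wf <- if (flat(wf) || flat(pd_vals)) NA_real_ else
    stats::cor(pd_vals, wf)
  if (!is.null(cspd_vals)) {
    cor_cspd_wf <- if (flat(wf) || flat(cspd_vals)) NA_real_ else
      stats::cor(cspd_vals, wf)
    cor_pd_cspd <- if (flat(pd_vals) || flat(cspd_vals)) NA_real_ else
      stats::cor(pd_vals, cspd_vals)
  }
  list(times = centers, pd_series = pd_vals, cspd_series = cspd_vals,
       waveform = wf,
       cor_pd_waveform = cor_pd_wf,
       cor_cspd_waveform = cor_cspd_wf,
       cor_pd_cspd = cor_pd_cspd)
}

#' Depth band where the vessel pair is unobstructed
#'
#' Finds the depth interval along the tagged parallel pair in which no
#' other vessel segment comes within `clearance` of the pair's lateral
#' neighborhood — the synthetic analogue of manually selecting an
#' unobstructed vessel for profile measurements. Returns the longest clear
#' interval.
#'
#' @param tree a `vessel_tree` containing the tagged pair.
#' @param clearance minimum lateral/axial distance (mm) from any non-pair
#'   segment.
#' @return numeric length-2 depth range in mm (errors if no clear depth
#'   exists).
#' @export
pair_clear_depths <- function(tree, clearance = 0.06) {
  tags <- vapply(tree$segments, function(s) s$tag, character(1))
  pair_idx <- which(tags %in% c("pair_a", "pair_b"))
  if (length(pair_idx) != 2L) stop_invalid("tree has no tagged parallel vessel pair")
  zs <- tree$segments[[pair_idx[1]]]$points[, 2]
  xr <- range(vapply(pair_idx, function(i) tree$segments[[i]]$points[1, 1],
                     numeric(1)))
  z_grid <- seq(min(zs), max(zs), length.out = 128L)
  clear <- rep(TRUE, length(z_grid))
  for (i in setdiff(seq_along(tree$segments), pair_idx)) {
    p <- tree$segments[[i]]$points
    # dense resample of the obstructing centerline
    L <- polyline_length(p)
    if (L <= 0) next
    q <- polyline_interp(p, seq(0, L, length.out = 256L))
    for (k in seq_along(z_grid)) {
      if (!clear[k]) next
      dx <- pmax(xr[1] - clearance - q[, 1], q[, 1] - xr[2] - clearance, 0)
      dz <- abs(q[, 2] - z_grid[k])
      if (any(dx == 0 & dz < clearance)) clear[k] <- FALSE
    }
  }
  if (!any(clear)) stop_invalid("no unobstructed depth along the vessel pair")
  r <- rle(clear)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which.max(ifelse(r$values, r$lengths, 0))
  range(z_grid[starts[best]:ends[best]])
}

#' Cross-sectional line through the sub-diffraction vessel pair
#'
#' Returns the evaluation line crossing the parallel vessel pair of a
#' [make_vessel_tree()] tree perpendicular at mid-depth (native-grid mm
#' coordinates), for profile-based resolution checks.
#'
#' @param tree a `vessel_tree` containing the tagged pair.
#' @param halfwidth lateral half-extent of the line in mm.
#' @return list with `p0`, `p1`, `orientation = "cross"`, and the pair
#'   lateral coordinates `x_pair`.
#' @export
pair_cross_line <- function(tree, halfwidth = 0.12) {
  tags <- vapply(tree$segments, function(s) s$tag, character(1))
  ia <- which(tags == "pair_a"); ib <- which(tags == "pair_b")
  if (length(ia) != 1L || length(ib) != 1L) {
    stop_invalid("tree has no tagged parallel vessel pair")
  }
  xa <- unname(tree$segments[[ia]]$points[1, 1])
  xb <- unname(tree$segments[[ib]]$points[1, 1])
  zm <- mean(range(tree$segments[[ia]]$points[, 2]))
  xc <- (xa + xb) / 2
  list(p0 = c(xc - halfwidth, zm), p1 = c(xc + halfwidth, zm),
       orientation = "cross", x_pair = c(xa, xb), z = zm)
}
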