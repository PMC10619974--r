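# The CS-PD model fit: translate short clutter-filtered spatiotemporal
# ultrasound ensembles into super-resolved microvessel images, trained
# against ULM accumulation maps. `cspd()` is the fitting function; the
# returned object supports print, summary, predict and plot.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 0.001, decayed by a factor of 0.1 when the validation loss stops
#' improving for five epochs, 50 epochs, 10% validation split; in
#' adversarial mode five critic steps per generator step with weight
#' clipping at 0.01.
#'
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor in (0, 1).
#' @param patience epochs without validation improvement before decay.
#' @param epochs maximum training epochs.
#' @param val_fraction validation fraction in (0, 1).
#' @param critic_steps critic updates per generator step (adversarial
#'   mode).
#' @param weight_clip critic weight clip bound.
#' @param seed master seed for the split, shuffling and initialization.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, lr_decay = 0.1, patience = 5L,
                         epochs = 50L, val_fraction = 0.1,
                         critic_steps = 5L, weight_clip = 0.01,
                         seed = 1L, verbose = FALSE) {
  if (lr_decay <= 0 || lr_decay >= 1) stop_invalid("`lr_decay` must be in (0, 1)")
  if (patience < 1L) stop_invalid("`patience` must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop_invalid("`val_fraction` must be in (0, 1)")
  }
  structure(as.list(environment()), class = "train_config")
}

#' Prepare a network input from a spatiotemporal block
#'
#' Takes the signal magnitude and normalizes by the block's 99th-percentile
#' magnitude (linear scale). In `"collapsed"` mode the block is first
#' accumulated into a single power Doppler image (the temporal-information
#' ablation baseline), normalized the same way.
#'
#' @param block a clutter-filtered `st_block`.
#' @param mode `"spatiotemporal"` (frames as channels) or `"collapsed"`.
#' @return array `(Z, X, T)` or `(Z, X, 1)`.
#' @export
prepare_input <- function(block, mode = c("spatiotemporal", "collapsed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(block, "st_block"))
  if (mode == "collapsed") {
    x <- power_doppler(block)$intensity
    x <- array(x, c(dim(x), 1L))
  } else {
    x <- Mod(block$data)
  }
  q <- stats::quantile(x, 0.99, names = FALSE)
  if (q > 0) x <- x / q
  attr(x, "scale") <- q     # the ensemble's power scale, undone on request
  x
}

# Normalize heterogeneous training inputs into a flat sample list.
as_training_samples <- function(data, input_mode) {
  planes <- data
  if (!is.null(planes$blocks) && !is.null(planes$ulm)) planes <- list(planes)
  samples <- list()
  for (pi in seq_along(planes)) {
    pl <- planes[[pi]]
    if (is.null(pl$blocks) || is.null(pl$ulm)) {
      stop_invalid("each training plane needs `blocks` and `ulm` fields")
    }
    y <- if (inherits(pl$ulm, "ulm_image")) pl$ulm$intensity else pl$ulm
    if (is.null(y)) stop_invalid("ULM target has no intensity; run normalize_ulm()")
    for (b in seq_along(pl$blocks)) {
      samples[[length(samples) + 1L]] <-
        list(x = prepare_input(pl$blocks[[b]], input_mode), y = y,
             plane = pi, block = b,
             pixel_pitch = pl$blocks[[b]]$pixel_pitch)
    }
  }
  samples
}

#' Fit a contrast-free super-resolution power Doppler model
#'
#' Trains the U-Net generator to translate clutter-filtered spatiotemporal
#' ultrasound blocks into super-resolved microvessel images, using ULM
#' accumulation maps as targets. A fixed fraction of the samples is held
#' out as a validation set before training; the learning rate decays when
#' the validation loss plateaus, and the parameters with the best
#' validation loss are returned. In adversarial mode the critic is updated
#' `critic_steps` times per generator step with weight clipping.
#'
#' @param data training planes: a list of objects with `blocks` (list of
#'   clutter-filtered `st_block`) and `ulm` (a normalized [accumulate_ulm()]
#'   image), e.g. from [make_training_pair()] or [build_dataset()].
#' @param generator a [generator_spec()]; `in_frames` is inferred from the
#'   data when `NULL`.
#' @param loss a [loss_spec()].
#' @param config a [train_config()].
#' @param input_mode `"spatiotemporal"` (slow-time frames as input
#'   channels) or `"collapsed"` (single accumulated power Doppler image,
#'   the ablation baseline).
#' @return object of class `cspd` with the trained `model`, the training
#'   `history` (data.frame epoch/train_loss/val_loss/lr), the
#'   configuration, and (in adversarial mode) the `critic`.
#' @seealso [predict.cspd()], [sliding_window_series()]
#' @export
cspd <- function(data, generator = NULL, loss = loss_spec("L1"),
                 config = train_config(),
                 input_mode = c("spatiotemporal", "collapsed")) {
  input_mode <- match.arg(input_mode)
  stopifnot(inherits(loss, "loss_spec"), inherits(config, "train_config"))
  samples <- as_training_samples(data, input_mode)
  n <- length(samples)
  if (n < 2L) stop_invalid("need at least 2 training samples (got %d)", n)
  d1 <- dim(samples[[1]]$x)
  if (is.null(generator)) {
    generator <- generator_spec(in_frames = d1[3], seed = config$seed)
  }
  if (generator$in_frames != d1[3]) {
    stop_invalid("generator expects %d input frames but samples have %d",
                 generator$in_frames, d1[3])
  }
  yd <- dim(samples[[1]]$y)
  if (!all(yd == generator$R * d1[1:2])) {
    stop_invalid("target grid %d x %d does not match R * input grid (%d x %d)",
                 yd[1], yd[2], generator$R * d1[1], generator$R * d1[2])
  }

  model <- build_generator(generator)
  opt <- adam_init(model$params)
  critic <- NULL; copt <- NULL
  if (loss$mode == "L1+ADV") {
    critic <- build_discriminator(yd, seed = config$seed + 1L)
    copt <- adam_init(critic$params)
  }

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  with_seed(config$seed, {
    n_val <- max(1L, round(config$val_fraction * n))
    if (n_val >= n) n_val <- n - 1L
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)

    lr <- config$lr
    best_val <- Inf
    best <- NULL
    wait <- 0L

    # validation objective: the non-adversarial part of the loss (the
    # adversarial term depends on the evolving critic)
    val_loss_fun <- function() {
      vs <- 0
      vspec <- if (loss$mode == "L1+ADV") loss_spec("L1") else loss
      for (i in val_idx) {
        fw <- generator_forward(model, samples[[i]]$x, train = FALSE)
        vs <- vs + compute_loss(fw$y, samples[[i]]$y, vspec)$total
      }
      vs / length(val_idx)
    }

    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(train_idx)
      tl <- 0
      for (i in order_idx) {
        if (loss$mode == "L1+ADV") {
          for (cs in seq_len(config$critic_steps)) {
            ri <- train_idx[sample.int(length(train_idx), 1L)]
            fake <- generator_forward(model, samples[[i]]$x, train = FALSE)$y
            fr <- critic_forward(critic, fake, keep_cache = TRUE)
            gr_f <- critic_backward(critic, fr$caches, 1)$grads
            rr <- critic_forward(critic, samples[[ri]]$y, keep_cache = TRUE)
            gr_r <- critic_backward(critic, rr$caches, -1)$grads
            g <- tree_map2(`+`, gr_f, gr_r)
            st <- adam_step(critic$params, g, copt, lr)
            critic$params <- st$params; copt <- st$opt
            critic <- clip_critic_weights(critic, config$weight_clip)
          }
        }
        fw <- generator_forward(model, samples[[i]]$x, train = TRUE)
        model$state <- fw$state
        ls <- compute_loss(fw$y, samples[[i]]$y, loss, critic,
                           with_grad = TRUE)
        if (!is.finite(ls$total)) {
          stop_invalid(paste0(
            "training aborted: non-finite loss at epoch %d, plane %d block %d",
            " (lr = %g, L1 = %g, feature = %g, adversarial = %g)"),
            epoch, samples[[i]]$plane, samples[[i]]$block, lr,
            ls$l1, ls$feature, ls$adversarial)
        }
        tl <- tl + ls$total
        grads <- generator_backward(model, fw$caches, ls$grad)
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params; opt <- st$opt
      }
      vl <- val_loss_fun()
      history[nrow(history) + 1L, ] <- list(epoch, tl / length(train_idx), vl, lr)
      if (config$verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %g",
                        epoch, tl / length(train_idx), vl, lr))
      }
      if (vl < best_val - 1e-12) {
        best_val <- vl
        best <- list(params = model$params, state = model$state)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          lr <- lr * config$lr_decay
          wait <- 0L
        }
      }
    }
    if (!is.null(best)) {
      model$params <- best$params
      model$state <- best$state
    }
  })
  n_val <- max(1L, min(round(config$val_fraction * n), n - 1L))
  structure(list(model = model, critic = critic, loss = loss,
                 config = config, generator = generator,
                 input_mode = input_mode, history = history,
                 n_samples = n, n_val = n_val, n_train = n - n_val,
                 best_val = min(history$val_loss),
                 pixel_pitch = samples[[1]]$pixel_pitch),
            class = "cspd")
}

#' @export
print.cspd <- function(x, ...) {
  cat("Contrast-free super-resolution power Doppler model\n")
  cat(sprintf("  loss: %s | input: %s | R = %d | %d samples (%d validation)\n",
              x$loss$mode, x$input_mode, x$generator$R, x$n_samples, x$n_val))
  cat(sprintf("  trained %d epochs; best validation loss %.5f\n",
              nrow(x$history), x$best_val))
  invisible(x)
}

#' @export
summary.cspd <- function(object, ...) {
  np <- sum(rapply(object$model$params, length, how = "unlist"))
  cat("Contrast-free super-resolution power Doppler model\n\n")
  cat(sprintf("Generator: %d input frames, %d levels, base %d channels, R = %d\n",
              object$generator$in_frames, object$generator$n_levels,
              object$generator$base_channels, object$generator$R))
  cat(sprintf("Parameters: %d\n", np))
  cat(sprintf("Objective: %s (lambda1 = %g, lambda2 = %g)\n",
              object$loss$mode, object$loss$lambda1, object$loss$lambda2))
  cat(sprintf("Training: %d epochs, lr %g (decay %g, patience %d), %d/%d train/val\n",
              nrow(object$history), object$config$lr, object$config$lr_decay,
              object$config$patience,
              object$n_samples - object$n_val, object$n_val))
  h <- object$history
  cat(sprintf("Loss: train %.5f -> %.5f, best validation %.5f (epoch %d)\n",
              h$train_loss[1], h$train_loss[nrow(h)], min(h$val_loss),
              h$epoch[which.min(h$val_loss)]))
  invisible(object)
}

#' Plot CS-PD training history
#'
#' @param x a fitted [cspd()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cspd <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Reconstruct a super-resolved image from a spatiotemporal block
#'
#' Runs the trained generator on a clutter-filtered block. Inference is
#' deterministic: normalization layers use their frozen running moments.
#' The output is nonnegative and scaled to `[0, 1]`.
#'
#' @param object a fitted [cspd()] model.
#' @param block a clutter-filtered `st_block` (frame count must equal the
#'   generator's `in_frames`; use [truncate_and_interpolate()] to adapt a
#'   shorter acquisition).
#' @param ... unused.
#' @return object of class `cspd_image`: `intensity` (`R*Z x R*X` in
#'   `[0, 1]`), `pixel_pitch` (fine grid, mm) and `R`.
#' @export
predict.cspd <- function(object, block, ...) {
  stopifnot(inherits(block, "st_block"))
  if (!identical(block$kind, "clutter_filtered")) {
    stop_invalid("`block` must be clutter_filtered")
  }
  x <- prepare_input(block, object$input_mode)
  if (dim(x)[3] != object$generator$in_frames) {
    stop_invalid("block has %d frames but the model expects %d; apply truncate_and_interpolate() first",
                 dim(x)[3], object$generator$in_frames)
  }
  fw <- generator_forward(object$model, x, train = FALSE)
  img <- fw$y[, , 1]
  m <- max(img)
  if (m > 0) img <- img / m
  structure(list(intensity = img, pixel_pitch = block$pixel_pitch / object$generator$R,
                 R = object$generator$R,
                 scale = m * (attr(x, "scale") %||% 1)),
            class = "cspd_image")
}

#' @export
print.cspd_image <- function(x, ...) {
  cat(sprintf("CS-PD image: %d x %d (R = %d, %.1f um pitch)\n",
              nrow(x$intensity), ncol(x$intensity), x$R, 1e3 * x$pixel_pitch))
  invisible(x)
}
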