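# Wasserstein critic and the pluggable feature extractor used by the
# feature-space loss. The critic maps a super-resolved image to a scalar
# score (no sigmoid); generator and critic are trained simultaneously by
# minimizing the approximation of the Earth-Mover distance, with weight
# clipping for the Lipschitz constraint.

#' Build the critic network
#'
#' One 3x3 input block, three downsampling blocks (a 3x3 convolution
#' followed by a stride-2 3x3 convolution), and a 3x3 output block mapping
#' to one channel whose spatial mean is the score. All activations are
#' leaky ReLU with negative slope 0.2.
#'
#' @param image_dim integer length-2 input image size (must be >= 8, i.e.
#'   survive three 2x downsamplings).
#' @param base_channels channels of the input block (doubling per
#'   downsampling block).
#' @param seed integer seed for initialization.
#' @return object of class `cspd_critic`.
#' @export
build_discriminator <- function(image_dim, base_channels = 8L, seed = 1L) {
  if (any(image_dim < 8L)) {
    stop_invalid("critic input must be at least 8 x 8, got %d x %d",
                 image_dim[1], image_dim[2])
  }
  ch <- base_channels * 2L^(0:3)
  with_seed(seed, {
    params <- list(inblk = conv_init(3L, 1L, ch[1]))
    params$down <- vector("list", 3L)
    for (i in 1:3) {
      params$down[[i]] <- list(conv1 = conv_init(3L, ch[i], ch[i + 1L]),
                               conv2 = conv_init(3L, ch[i + 1L], ch[i + 1L]))
    }
    params$outblk <- conv_init(3L, ch[4], 1L)
    structure(list(params = params, image_dim = as.integer(image_dim),
                   base_channels = as.integer(base_channels), seed = seed),
              class = "cspd_critic")
  })
}

#' @export
print.cspd_critic <- function(x, ...) {
  cat(sprintf("CS-PD critic: %d x %d input, base %d channels\n",
              x$image_dim[1], x$image_dim[2], x$base_channels))
  invisible(x)
}

# stride-2 3x3 convolution realized as stride-1 conv + 2x subsampling
conv_s2_fwd <- function(x, par) {
  cv <- conv_fwd(x, par, k = 3L)
  d <- dim(cv$y)
  y <- cv$y[seq(1L, d[1], 2L), seq(1L, d[2], 2L), , drop = FALSE]
  list(y = y, cache = list(conv = cv$cache, dim = d))
}
conv_s2_bwd <- function(dy, cache) {
  d <- cache$dim
  full <- array(0, d)
  full[seq(1L, d[1], 2L), seq(1L, d[2], 2L), ] <- dy
  conv_bwd(full, cache$conv)
}

#' Critic forward pass
#'
#' @param critic a `cspd_critic`.
#' @param x image array `(H, W, 1)` or matrix.
#' @param keep_cache record caches for backprop.
#' @return list with scalar `score` and `caches`.
#' @export
critic_forward <- function(critic, x, keep_cache = FALSE) {
  x <- as_hwc(x)
  par <- critic$params
  caches <- list()
  cv <- conv_fwd(x, par$inblk, k = 3L)
  a <- lrelu_fwd(cv$y)
  caches$inblk <- list(conv = cv$cache, act = a$cache)
  h <- a$y
  caches$down <- vector("list", 3L)
  for (i in 1:3) {
    c1 <- conv_fwd(h, par$down[[i]]$conv1, k = 3L)
    a1 <- lrelu_fwd(c1$y)
    c2 <- conv_s2_fwd(a1$y, par$down[[i]]$conv2)
    a2 <- lrelu_fwd(c2$y)
    caches$down[[i]] <- list(conv1 = c1$cache, act1 = a1$cache,
                             conv2 = c2$cache, act2 = a2$cache)
    h <- a2$y
  }
  co <- conv_fwd(h, par$outblk, k = 3L)
  ao <- lrelu_fwd(co$y)
  caches$outblk <- list(conv = co$cache, act = ao$cache, dim = dim(ao$y))
  score <- mean(ao$y)
  list(score = score, caches = if (keep_cache) caches else NULL)
}

#' Critic backward pass
#'
#' Backpropagates `dscore` (gradient of the loss w.r.t. the scalar score)
#' through the critic.
#'
#' @param critic a `cspd_critic`.
#' @param caches caches from [critic_forward()].
#' @param dscore scalar gradient.
#' @return list with `grads` (matching `critic$params`) and `dx` (gradient
#'   w.r.t. the input image).
#' @export
critic_backward <- function(critic, caches, dscore) {
  dmap <- array(dscore / prod(caches$outblk$dim), caches$outblk$dim)
  dmap <- lrelu_bwd(dmap, caches$outblk$act)
  ob <- conv_bwd(dmap, caches$outblk$conv)
  grads <- list(inblk = NULL, down = vector("list", 3L),
                outblk = list(W = ob$dW, b = ob$db))
  dh <- ob$dx
  for (i in 3:1) {
    dc <- caches$down[[i]]
    dh <- lrelu_bwd(dh, dc$act2)
    b2 <- conv_s2_bwd(dh, dc$conv2)
    da <- lrelu_bwd(b2$dx, dc$act1)
    b1 <- conv_bwd(da, dc$conv1)
    grads$down[[i]] <- list(conv1 = list(W = b1$dW, b = b1$db),
                            conv2 = list(W = b2$dW, b = b2$db))
    dh <- b1$dx
  }
  dh <- lrelu_bwd(dh, caches$inblk$act)
  ib <- conv_bwd(dh, caches$inblk$conv)
  grads$inblk <- list(W = ib$dW, b = ib$db)
  list(grads = list(inblk = grads$inblk, down = grads$down,
                    outblk = grads$outblk),
       dx = ib$dx)
}

#' Clip critic weights
#'
#' Projects every parameter into `[-bound, bound]` (the Lipschitz
#' constraint of weight-clipped Wasserstein training).
#'
#' @param critic a `cspd_critic`.
#' @param bound clip bound `c > 0` (default 0.01).
#' @return the clipped critic.
#' @export
clip_critic_weights <- function(critic, bound = 0.01) {
  critic$params <- tree_map(function(p) pmin(pmax(p, -bound), bound),
                            critic$params)
  critic
}

#' Fixed convolutional feature extractor
#'
#' A seeded, untrained two-stage convolutional stack (3x3 conv + ReLU,
#' 16 then 32 channels) whose feature maps define the feature-space loss.
#' Random fixed convolutional features are a documented, download-free
#' default; any extractor exposing the same interface (a `forward` with
#' input gradients) can be plugged in instead.
#'
#' @param seed integer seed.
#' @param channels integer vector of channel widths per stage.
#' @return object of class `feature_extractor`.
#' @export
feature_extractor <- function(seed = 7L, channels = c(16L, 32L)) {
  with_seed(seed, {
    par <- list()
    cin <- 1L
    for (i in seq_along(channels)) {
      par[[i]] <- conv_init(3L, cin, channels[i])
      cin <- channels[i]
    }
    structure(list(params = par, channels = channels, seed = seed),
              class = "feature_extractor")
  })
}

feature_forward <- function(fe, x, keep_cache = FALSE) {
  x <- as_hwc(x)
  caches <- vector("list", length(fe$params))
  h <- x
  for (i in seq_along(fe$params)) {
    cv <- conv_fwd(h, fe$params[[i]], k = 3L)
    a <- relu_fwd(cv$y)
    caches[[i]] <- list(conv = cv$cache, act = a$cache)
    h <- a$y
  }
  list(y = h, caches = if (keep_cache) caches else NULL)
}

# gradient w.r.t. the input only (the extractor is frozen)
feature_backward <- function(fe, caches, dy) {
  for (i in rev(seq_along(fe$params))) {
    dy <- relu_bwd(dy, caches[[i]]$act)
    dy <- conv_bwd(dy, caches[[i]]$conv)$dx
  }
  dy
}
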