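# The CS-PD generator: a U-Net encoder-decoder that maps a spatiotemporal
# ensemble (slow-time frames entering as input channels) to a single
# super-resolved image on an R-fold upsampled grid. Encoding blocks are two
# 3x3 convolutions with channelwise normalization and ReLU followed by 2x2
# max pooling; decoding blocks are a 2x2 stride-2 transposed convolution, a
# skip concatenation (with bilinear upsampling of the encoder feature when
# grids differ), and two 3x3 convolutions; extra 2x2 bilinear upsampling
# stages after the last decoding blocks provide the output upsampling
# factor R = 2^n_extra_upsamples. The final layer is a 1x1 convolution with
# a softplus rectifier, so the output intensity is nonnegative while the
# training gradient never vanishes exactly (a hard ReLU output dies on
# mostly-zero super-resolution targets).

#' Generator architecture specification
#'
#' @param in_frames number of slow-time frames entering as input channels.
#' @param n_levels number of encoding/decoding blocks (pooling steps).
#' @param base_channels channels of the first encoding block; widths double
#'   per level.
#' @param n_extra_upsamples extra bilinear 2x stages appended to the last
#'   decoding blocks; the output upsampling factor is
#'   `R = 2^n_extra_upsamples`. Must not exceed `n_levels`.
#' @param seed integer seed for parameter initialization.
#' @return object of class `generator_spec` (with derived field `R`).
#' @export
generator_spec <- function(in_frames = 16L, n_levels = 2L, base_channels = 8L,
                           n_extra_upsamples = 2L, seed = 1L) {
  if (n_levels < 1L) stop_invalid("`n_levels` must be >= 1")
  if (n_extra_upsamples < 0L || n_extra_upsamples > n_levels) {
    stop_invalid("`n_extra_upsamples` must be in [0, n_levels]")
  }
  structure(list(in_frames = as.integer(in_frames),
                 n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 n_extra_upsamples = as.integer(n_extra_upsamples),
                 R = 2L^as.integer(n_extra_upsamples),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

enc_block_init <- function(cin, cout) {
  list(conv1 = c(conv_init(3L, cin, cout, bias = FALSE), bn_init(cout)),
       conv2 = c(conv_init(3L, cout, cout, bias = FALSE), bn_init(cout)))
}
enc_block_state <- function(cout) {
  list(conv1 = bn_state_init(cout), conv2 = bn_state_init(cout))
}

#' Build an untrained CS-PD generator
#'
#' Parameters are He-initialized under the spec seed, so two builds with
#' the same spec are bitwise identical.
#'
#' @param spec a [generator_spec()].
#' @return object of class `cspd_model` with nested `params`, normalization
#'   `state`, and the `spec`.
#' @export
#' @examples
#' m <- build_generator(generator_spec(in_frames = 4, base_channels = 4))
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  L <- spec$n_levels
  ch <- spec$base_channels * 2L^(0:L)      # ch[i] = channels of level i
  with_seed(spec$seed, {
    params <- list()
    state <- list()
    params$enc <- vector("list", L)
    state$enc <- vector("list", L)
    cin <- spec$in_frames
    for (i in seq_len(L)) {
      params$enc[[i]] <- enc_block_init(cin, ch[i])
      state$enc[[i]] <- enc_block_state(ch[i])
      cin <- ch[i]
    }
    params$bottom <- enc_block_init(ch[L], ch[L + 1L])
    state$bottom <- enc_block_state(ch[L + 1L])
    params$dec <- vector("list", L)
    state$dec <- vector("list", L)
    for (j in seq_len(L)) {
      cskip <- ch[L + 1L - j]
      cup <- ch[L + 2L - j]
      params$dec[[j]] <- list(
        tconv = tconv_init(cup, cskip),
        conv1 = c(conv_init(3L, 2L * cskip, cskip, bias = FALSE), bn_init(cskip)),
        conv2 = c(conv_init(3L, cskip, cskip, bias = FALSE), bn_init(cskip)))
      state$dec[[j]] <- enc_block_state(cskip)
    }
    params$final <- conv_init(1L, ch[1], 1L)
    params$final$b[] <- -4                 # start with a near-zero background
    structure(list(params = params, state = state, spec = spec),
              class = "cspd_model")
  })
}

#' @export
print.cspd_model <- function(x, ...) {
  np <- sum(vapply(tree_leaves(x$params), length, numeric(1)))
  cat(sprintf(
    "CS-PD generator: %d input frames, %d levels, base %d channels, R = %d (%d parameters)\n",
    x$spec$in_frames, x$spec$n_levels, x$spec$base_channels, x$spec$R,
    length(tree_leaves(x$params))))
  invisible(x)
}

conv_bn_relu_fwd <- function(x, par, st, train) {
  cv <- conv_fwd(x, par, k = 3L)
  bn <- bn_fwd(cv$y, par, st, train)
  rl <- relu_fwd(bn$y)
  list(y = rl$y, state = bn$state,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

conv_bn_relu_bwd <- function(dy, cache) {
  dy <- relu_bwd(dy, cache$relu)
  bb <- bn_bwd(dy, cache$bn)
  cb <- conv_bwd(bb$dx, cache$conv)
  list(dx = cb$dx,
       grad = list(W = cb$dW, gamma = bb$dgamma, beta = bb$dbeta))
}

enc_block_fwd <- function(x, par, st, train) {
  c1 <- conv_bn_relu_fwd(x, par$conv1, st$conv1, train)
  c2 <- conv_bn_relu_fwd(c1$y, par$conv2, st$conv2, train)
  list(y = c2$y, state = list(conv1 = c1$state, conv2 = c2$state),
       cache = list(conv1 = c1$cache, conv2 = c2$cache))
}

enc_block_bwd <- function(dy, cache) {
  b2 <- conv_bn_relu_bwd(dy, cache$conv2)
  b1 <- conv_bn_relu_bwd(b2$dx, cache$conv1)
  list(dx = b1$dx, grad = list(conv1 = b1$grad, conv2 = b2$grad))
}

#' Generator forward pass
#'
#' @param model a `cspd_model`.
#' @param x input array `(H, W, T)` with `T = spec$in_frames` and `H`, `W`
#'   divisible by `2^n_levels`.
#' @param train use batch statistics and record caches for backprop.
#' @return list with `y` (`R*H x R*W x 1` nonnegative array), updated
#'   `state`, and `caches` (when `train = TRUE` or `keep_cache = TRUE`).
#' @param keep_cache record caches even in evaluation mode.
#' @export
generator_forward <- function(model, x, train = FALSE, keep_cache = train) {
  spec <- model$spec
  x <- as_hwc(x)
  d <- dim(x)
  div <- 2L^spec$n_levels
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop_invalid(paste0(
      "input %d x %d not divisible by 2^n_levels = %d; pad to %d x %d"),
      d[1], d[2], div, ceiling(d[1] / div) * div, ceiling(d[2] / div) * div)
  }
  if (d[3] != spec$in_frames) {
    stop_invalid("input has %d frames but the generator expects %d; use truncate_and_interpolate() to match",
                 d[3], spec$in_frames)
  }
  L <- spec$n_levels
  par <- model$params
  st <- model$state
  caches <- list(enc = vector("list", L), pool = vector("list", L),
                 dec = vector("list", L))
  skips <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    eb <- enc_block_fwd(h, par$enc[[i]], st$enc[[i]], train)
    st$enc[[i]] <- eb$state
    caches$enc[[i]] <- eb$cache
    skips[[i]] <- eb$y
    mp <- maxpool_fwd(eb$y)
    caches$pool[[i]] <- mp$cache
    h <- mp$y
  }
  bb <- enc_block_fwd(h, par$bottom, st$bottom, train)
  st$bottom <- bb$state
  caches$bottom <- bb$cache
  h <- bb$y

  extra_from <- L - spec$n_extra_upsamples + 1L   # decode blocks with extra 2x
  extra_acc <- 0L                                  # accumulated extra factor (log2)
  for (j in seq_len(L)) {
    dc <- list()
    tc <- tconv_fwd(h, par$dec[[j]]$tconv)
    dc$tconv <- tc$cache
    skip <- skips[[L + 1L - j]]
    if (extra_acc > 0L) {
      us <- upsample_pow2_fwd(skip, extra_acc)
      dc$skip_up <- us$cache
      skip <- us$y
    }
    cc <- concat_fwd(tc$y, skip)
    dc$concat <- cc$cache
    c1 <- conv_bn_relu_fwd(cc$y, par$dec[[j]]$conv1, st$dec[[j]]$conv1, train)
    st$dec[[j]]$conv1 <- c1$state
    dc$conv1 <- c1$cache
    c2 <- conv_bn_relu_fwd(c1$y, par$dec[[j]]$conv2, st$dec[[j]]$conv2, train)
    st$dec[[j]]$conv2 <- c2$state
    dc$conv2 <- c2$cache
    h <- c2$y
    if (j >= extra_from) {
      ex <- upsample2_fwd(h)
      dc$extra <- ex$cache
      h <- ex$y
      extra_acc <- extra_acc + 1L
    }
    caches$dec[[j]] <- dc
  }
  fc <- conv_fwd(h, par$final, k = 1L)
  caches$final <- fc$cache
  out <- softplus_fwd(fc$y)
  caches$out_act <- out$cache
  list(y = out$y, state = st, caches = if (keep_cache) caches else NULL)
}

#' Generator backward pass
#'
#' @param model the `cspd_model` used for the forward pass.
#' @param caches caches returned by [generator_forward()] with
#'   `train = TRUE`.
#' @param dy gradient of the loss with respect to the output.
#' @return nested gradient list matching `model$params`.
#' @export
generator_backward <- function(model, caches, dy) {
  spec <- model$spec
  L <- spec$n_levels
  grads <- list(enc = vector("list", L), dec = vector("list", L))
  dy <- softplus_bwd(dy, caches$out_act)
  fb <- conv_bwd(dy, caches$final)
  grads$final <- list(W = fb$dW, b = fb$db)
  dh <- fb$dx
  dskips <- vector("list", L)
  extra_from <- L - spec$n_extra_upsamples + 1L
  for (j in rev(seq_len(L))) {
    dc <- caches$dec[[j]]
    if (!is.null(dc$extra)) dh <- upsample2_bwd(dh, dc$extra)
    b2 <- conv_bn_relu_bwd(dh, dc$conv2)
    b1 <- conv_bn_relu_bwd(b2$dx, dc$conv1)
    sp <- concat_bwd(b1$dx, dc$concat)
    dskip <- sp$db
    if (!is.null(dc$skip_up)) dskip <- upsample_pow2_bwd(dskip, dc$skip_up)
    dskips[[L + 1L - j]] <- dskip
    tb <- tconv_bwd(sp$da, dc$tconv)
    grads$dec[[j]] <- list(tconv = list(W = tb$dW),
                           conv1 = b1$grad, conv2 = b2$grad)
    dh <- tb$dx
  }
  bb <- enc_block_bwd(dh, caches$bottom)
  grads$bottom <- bb$grad
  dh <- bb$dx
  for (i in rev(seq_len(L))) {
    dh <- maxpool_bwd(dh, caches$pool[[i]])
    dh <- dh + dskips[[i]]
    eb <- enc_block_bwd(dh, caches$enc[[i]])
    grads$enc[[i]] <- eb$grad
    dh <- eb$dx
  }
  # reorder to match params element order (enc, bottom, dec, final)
  list(enc = grads$enc, bottom = grads$bottom, dec = grads$dec,
       final = grads$final)
}
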