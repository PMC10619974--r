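# Differentiable primitives for the convolutional generator/critic.
# Feature maps are numeric arrays (H, W, C); convolutions use im2col plus
# BLAS matrix multiplication. Each *_fwd returns list(y, cache); each *_bwd
# consumes the upstream gradient and the cache and returns the input
# gradient plus parameter gradients. Everything is plain base R.

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

im2col <- function(x, k, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  cols <- matrix(0, H * W, k * k * C)
  idx <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    cols[, idx + seq_len(C)] <-
      matrix(xp[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, , drop = FALSE], H * W, C)
    idx <- idx + C
  }
  cols
}

# weight W: (k*k*Cin) x Cout; bias b: Cout. Convolutions feeding a
# normalization layer are built without a bias (it would be removed by the
# normalization and its gradient would be identically zero).
conv_init <- function(k, cin, cout, bias = TRUE) {
  out <- list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                         k * k * cin, cout))
  if (bias) out$b <- rep(0, cout)
  out
}

conv_fwd <- function(x, par, k = 3L) {
  x <- as_hwc(x)
  d <- dim(x)
  pad <- (k - 1L) %/% 2L
  cols <- if (k == 1L) matrix(x, d[1] * d[2], d[3]) else im2col(x, k, pad)
  y <- cols %*% par$W
  if (!is.null(par$b)) y <- sweep(y, 2L, par$b, "+")
  list(y = array(y, c(d[1], d[2], ncol(par$W))),
       cache = list(cols = cols, dim = d, k = k, pad = pad, W = par$W,
                    has_bias = !is.null(par$b)))
}

conv_bwd <- function(dy, cache) {
  d <- cache$dim
  cout <- length(dy) / (d[1] * d[2])
  dyM <- matrix(dy, d[1] * d[2], cout)
  dW <- crossprod(cache$cols, dyM)
  db <- if (cache$has_bias) colSums(dyM) else NULL
  if (cache$k == 1L) {
    dx <- array(tcrossprod(dyM, cache$W), d)
  } else {
    # input gradient = convolution of dy with the spatially flipped,
    # channel-transposed kernel (cheaper than scatter-accumulation)
    k2 <- cache$k^2
    A <- array(cache$W, c(d[3], k2, cout))
    Wrot <- matrix(aperm(A[, k2:1, , drop = FALSE], c(3, 2, 1)),
                   k2 * cout, d[3])
    dx <- array(im2col(array(dy, c(d[1], d[2], cout)), cache$k, cache$pad) %*% Wrot,
                d)
  }
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}
relu_bwd <- function(dy, cache) dy * cache

# smooth rectifier used as the generator's output activation: nonnegative
# output with a gradient that never vanishes exactly (a hard ReLU dies on
# sparse targets: once every pre-activation is negative, training stalls)
softplus_fwd <- function(x) {
  y <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  list(y = y, cache = x)
}
softplus_bwd <- function(dy, cache) {
  dy * stats::plogis(cache)
}

lrelu_fwd <- function(x, slope = 0.2) {
  m <- x > 0
  list(y = ifelse(m, x, slope * x), cache = list(m = m, slope = slope))
}
lrelu_bwd <- function(dy, cache) dy * ifelse(cache$m, 1, cache$slope)

# Channelwise normalization over the spatial pixel batch, with running
# moments for inference (the conv blocks train with a batch of one sample,
# so the normalization batch is the H*W pixel set of each channel).
bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c))
}
bn_state_init <- function(c) {
  list(mean = rep(0, c), var = rep(1, c), n = 0L)
}

bn_fwd <- function(x, par, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]
  xm <- matrix(x, N, d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    state$mean <- if (state$n == 0L) mu else (1 - momentum) * state$mean + momentum * mu
    state$var <- if (state$n == 0L) v else (1 - momentum) * state$var + momentum * v
    state$n <- state$n + 1L
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  list(y = array(y, d), state = state,
       cache = list(xhat = xhat, invstd = invstd, dim = d, gamma = par$gamma,
                    train = train))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dim; N <- d[1] * d[2]
  dyM <- matrix(dy, N, d[3])
  dgamma <- colSums(dyM * cache$xhat)
  dbeta <- colSums(dyM)
  if (cache$train) {
    dxhat <- sweep(dyM, 2L, cache$gamma, "*")
    t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2L, cache$invstd, "*")
  } else {
    dx <- sweep(sweep(dyM, 2L, cache$gamma, "*"), 2L, cache$invstd, "*")
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  cand <- array(NA_real_, c(H2, W2, d[3], 4L))
  p <- 0L
  for (b in 0:1) for (a in 0:1) {
    p <- p + 1L
    cand[, , , p] <- x[seq(1L, d[1], 2L) + a, seq(1L, d[2], 2L) + b, , drop = FALSE]
  }
  y <- pmax(cand[, , , 1], cand[, , , 2], cand[, , , 3], cand[, , , 4])
  arg <- array(1L, c(H2, W2, d[3]))
  best <- cand[, , , 1]
  for (p in 2:4) {
    better <- cand[, , , p] > best
    arg[better] <- p
    best[better] <- cand[, , , p][better]
  }
  list(y = y, cache = list(arg = arg, dim = d))
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dim
  dx <- array(0, d)
  p <- 0L
  for (b in 0:1) for (a in 0:1) {
    p <- p + 1L
    sel <- cache$arg == p
    sub <- array(0, dim(cache$arg))
    sub[sel] <- dy[sel]
    dx[seq(1L, d[1], 2L) + a, seq(1L, d[2], 2L) + b, ] <-
      dx[seq(1L, d[1], 2L) + a, seq(1L, d[2], 2L) + b, , drop = FALSE] + sub
  }
  dx
}

# 2x2 stride-2 transposed convolution; weights (2, 2, Cin, Cout). No bias:
# the following conv + normalization stage would absorb it.
tconv_init <- function(cin, cout) {
  list(W = array(stats::rnorm(4 * cin * cout, 0, sqrt(2 / cin)),
                 c(2L, 2L, cin, cout)))
}

tconv_fwd <- function(x, par) {
  d <- dim(x)
  cin <- d[3]; cout <- dim(par$W)[4]
  xM <- matrix(x, d[1] * d[2], cin)
  y <- array(0, c(2L * d[1], 2L * d[2], cout))
  for (a in 1:2) for (b in 1:2) {
    sub <- xM %*% matrix(par$W[a, b, , ], cin, cout)
    y[seq(1L, 2L * d[1], 2L) + a - 1L, seq(1L, 2L * d[2], 2L) + b - 1L, ] <-
      array(sub, c(d[1], d[2], cout))
  }
  list(y = y, cache = list(xM = xM, dim = d, W = par$W))
}

tconv_bwd <- function(dy, cache) {
  d <- cache$dim
  cin <- d[3]; cout <- dim(cache$W)[4]
  dW <- array(0, dim(cache$W))
  dxM <- matrix(0, d[1] * d[2], cin)
  for (a in 1:2) for (b in 1:2) {
    sub <- matrix(dy[seq(1L, 2L * d[1], 2L) + a - 1L,
                     seq(1L, 2L * d[2], 2L) + b - 1L, , drop = FALSE],
                  d[1] * d[2], cout)
    dW[a, b, , ] <- crossprod(cache$xM, sub)
    dxM <- dxM + tcrossprod(sub, matrix(cache$W[a, b, , ], cin, cout))
  }
  list(dx = array(dxM, d), dW = dW)
}

# Bilinear 2x upsampling matrices, memoized per input length.
.upsample_cache <- new.env(parent = emptyenv())
upsample2_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.upsample_cache[[key]])) return(.upsample_cache[[key]])
  A <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    src <- (i - 0.5) / 2 - 0.5           # 0-based source coordinate
    lo <- floor(src)
    w <- src - lo
    lo_c <- min(max(lo, 0), n - 1)
    hi_c <- min(max(lo + 1, 0), n - 1)
    A[i, lo_c + 1L] <- A[i, lo_c + 1L] + (1 - w)
    A[i, hi_c + 1L] <- A[i, hi_c + 1L] + w
  }
  .upsample_cache[[key]] <- A
  A
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  A <- upsample2_matrix(d[1])
  B <- upsample2_matrix(d[2])
  y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  for (c in seq_len(d[3])) y[, , c] <- A %*% x[, , c] %*% t(B)
  list(y = y, cache = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- cache
  A <- upsample2_matrix(d[1])
  B <- upsample2_matrix(d[2])
  dx <- array(0, d)
  for (c in seq_len(d[3])) dx[, , c] <- t(A) %*% dy[, , c] %*% B
  dx
}

# Repeated bilinear 2x upsampling (factor = 2^times).
upsample_pow2_fwd <- function(x, times) {
  caches <- vector("list", times)
  for (i in seq_len(times)) {
    r <- upsample2_fwd(x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, cache = caches)
}
upsample_pow2_bwd <- function(dy, cache) {
  for (i in rev(seq_along(cache))) dy <- upsample2_bwd(dy, cache[[i]])
  dy
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  list(y = y, cache = c(da[3], db[3]))
}
concat_bwd <- function(dy, cache) {
  list(da = dy[, , seq_len(cache[1]), drop = FALSE],
       db = dy[, , cache[1] + seq_len(cache[2]), drop = FALSE])
}

# Structure-preserving numeric-leaf map over nested parameter lists.
tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(el) tree_map(f, el)))
  f(a)
}
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}
tree_leaves <- function(a) {
  if (is.list(a)) return(unlist(lapply(a, tree_leaves), use.names = FALSE))
  as.numeric(a)
}

# Adam optimizer state and update over a nested parameter tree.
adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  step_leaf <- function(p, mv) p - lr * (mv$m / bc1) / (sqrt(mv$v / bc2) + eps)
  params <- rec_step(params, opt$m, opt$v, lr, bc1, bc2, eps)
  list(params = params, opt = opt)
}

rec_step <- function(p, m, v, lr, bc1, bc2, eps) {
  if (is.list(p)) {
    return(mapply(function(pp, mm, vv) rec_step(pp, mm, vv, lr, bc1, bc2, eps),
                  p, m, v, SIMPLIFY = FALSE))
  }
  p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
}
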