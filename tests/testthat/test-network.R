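# Generator/critic architecture contracts, gradient flow, losses, and a
# training smoke test.

tiny_input <- function(H = 16, W = 16, Tn = 3, seed = 1) {
  withr::with_seed(seed, array(runif(H * W * Tn), c(H, W, Tn)))
}

test_that("the generator honors the (T, Z, X) -> (1, R Z, R X) shape contract", {
  for (cfg in list(c(levels = 1, extra = 0), c(levels = 2, extra = 1),
                   c(levels = 2, extra = 2), c(levels = 3, extra = 2))) {
    spec <- generator_spec(in_frames = 3, n_levels = cfg["levels"],
                           base_channels = 2,
                           n_extra_upsamples = cfg["extra"], seed = 1)
    m <- build_generator(spec)
    x <- tiny_input(16, 16, 3)
    y <- generator_forward(m, x)$y
    expect_equal(dim(y), c(16L * spec$R, 16L * spec$R, 1L))
    expect_true(all(y >= 0))
  }
  expect_error(generator_spec(n_levels = 2, n_extra_upsamples = 3),
               "n_extra_upsamples")
})

test_that("indivisible input dimensions are rejected with the required padding", {
  m <- build_generator(generator_spec(in_frames = 2, n_levels = 2,
                                      base_channels = 2))
  expect_error(generator_forward(m, array(0, c(15, 16, 2))), "pad to 16 x 16")
  expect_error(generator_forward(m, array(0, c(16, 16, 5))),
               "truncate_and_interpolate")
})

test_that("two builds from one spec are bitwise identical and inference is deterministic", {
  spec <- generator_spec(in_frames = 2, n_levels = 2, base_channels = 4,
                         seed = 42)
  m1 <- build_generator(spec)
  m2 <- build_generator(spec)
  expect_identical(m1$params, m2$params)
  x <- tiny_input(16, 16, 2)
  expect_identical(generator_forward(m1, x)$y, generator_forward(m1, x)$y)
})

test_that("a forward/backward pass yields finite, non-degenerate gradients everywhere", {
  spec <- generator_spec(in_frames = 3, n_levels = 2, base_channels = 4,
                         n_extra_upsamples = 2, seed = 2)
  m <- build_generator(spec)
  x <- tiny_input(16, 16, 3, seed = 3)
  fw <- generator_forward(m, x, train = TRUE)
  target <- withr::with_seed(4, array(runif(length(fw$y)), dim(fw$y)))
  ls <- compute_loss(fw$y, target, loss_spec("L1"), with_grad = TRUE)
  grads <- generator_backward(m, fw$caches, ls$grad)
  walk <- function(g, path = "") {
    if (is.list(g)) {
      for (nm in seq_along(g)) walk(g[[nm]], paste0(path, "/", nm))
    } else {
      expect_true(all(is.finite(g)), info = path)
      expect_gt(sum(abs(g)), 0)
    }
  }
  walk(grads)
})

test_that("gradient trees mirror the parameter trees node for node", {
  # a structural mismatch would silently corrupt optimizer updates
  same_shape <- function(p, g, path = "") {
    expect_identical(is.list(p), is.list(g), info = path)
    if (is.list(p)) {
      expect_identical(names(p), names(g), info = path)
      for (i in seq_along(p)) {
        same_shape(p[[i]], g[[i]], paste0(path, "/", names(p)[i]))
      }
    } else {
      expect_identical(length(p), length(g), info = path)
    }
  }
  spec <- generator_spec(in_frames = 2, n_levels = 2, base_channels = 4,
                         n_extra_upsamples = 1, seed = 1)
  m <- build_generator(spec)
  x <- tiny_input(16, 16, 2, seed = 20)
  fw <- generator_forward(m, x, train = TRUE)
  ls <- compute_loss(fw$y, array(0.2, dim(fw$y)), loss_spec("L1"),
                     with_grad = TRUE)
  same_shape(m$params, generator_backward(m, fw$caches, ls$grad))

  cr <- build_discriminator(c(32, 32), base_channels = 2, seed = 2)
  cf <- critic_forward(cr, fw$y, keep_cache = TRUE)
  same_shape(cr$params, critic_backward(cr, cf$caches, 1)$grads)
})

test_that("the critic maps images to a single deterministic score and clips", {
  cr <- build_discriminator(c(32, 32), base_channels = 2, seed = 5)
  x <- tiny_input(32, 32, 1, seed = 6)
  s1 <- critic_forward(cr, x)$score
  s2 <- critic_forward(cr, x)$score
  expect_length(s1, 1)
  expect_identical(s1, s2)
  crc <- clip_critic_weights(cr, 0.01)
  leaves <- rapply(crc$params, function(p) max(abs(p)), how = "unlist")
  expect_true(all(leaves <= 0.01 + 1e-15))
  expect_error(build_discriminator(c(4, 4)), "at least 8 x 8")
})

test_that("a briefly trained critic separates real targets from generated images", {
  spec <- generator_spec(in_frames = 2, n_levels = 2, base_channels = 4,
                         n_extra_upsamples = 1, seed = 7)
  m <- build_generator(spec)
  cr <- build_discriminator(c(32, 32), base_channels = 4, seed = 8)
  copt <- cspd:::adam_init(cr$params)
  real <- withr::with_seed(9, {
    r <- matrix(0, 32, 32); r[, 14:16] <- 1; r
  })
  x <- tiny_input(16, 16, 2, seed = 10)
  fake <- generator_forward(m, x)$y
  for (i in 1:25) {
    fr <- critic_forward(cr, fake, keep_cache = TRUE)
    gf <- critic_backward(cr, fr$caches, 1)$grads
    rr <- critic_forward(cr, real, keep_cache = TRUE)
    gr <- critic_backward(cr, rr$caches, -1)$grads
    g <- cspd:::tree_map2(`+`, gf, gr)
    st <- cspd:::adam_step(cr$params, g, copt, 0.001)
    cr$params <- st$params; copt <- st$opt
    cr <- clip_critic_weights(cr, 0.01)
  }
  expect_gt(critic_forward(cr, real)$score,
            critic_forward(cr, fake[, , 1])$score)
})

test_that("loss components follow their closed forms and recompose", {
  a <- matrix(0.5, 16, 16)
  l <- compute_loss(a, a, loss_spec("L1"))
  expect_equal(l$l1, 0)
  l <- compute_loss(a + 0.1, a, loss_spec("L1"))
  expect_equal(l$l1, 0.1, tolerance = 1e-12)
  expect_equal(l$total, 0.1, tolerance = 1e-12)

  spec <- loss_spec("L1+VGG", lambda1 = 0.001)
  b <- withr::with_seed(11, matrix(runif(256), 16, 16))
  lv <- compute_loss(a, b, spec)
  fa <- cspd:::feature_forward(spec$extractor, a)$y
  fb <- cspd:::feature_forward(spec$extractor, b)$y
  feat <- mean((fa - fb)^2)
  expect_equal(lv$feature, feat, tolerance = 1e-12)
  expect_equal(lv$total, lv$l1 + 0.001 * feat, tolerance = 1e-12)
  expect_error(compute_loss(a, matrix(0, 4, 4), loss_spec("L1")), "shape")
  expect_error(compute_loss(a, b, loss_spec("L1+ADV")), "critic")
})

test_that("adversarial gradients point along the critic's input sensitivity", {
  cr <- build_discriminator(c(16, 16), base_channels = 2, seed = 12)
  a <- tiny_input(16, 16, 1, seed = 13)[, , 1]
  b <- a * 0
  spec <- loss_spec("L1+ADV", lambda2 = 0.01)
  l <- compute_loss(a, b, spec, critic = cr, with_grad = TRUE)
  expect_equal(l$adversarial, -critic_forward(cr, a)$score, tolerance = 1e-12)
  num <- function(i, eps = 1e-6) {
    ap <- a; ap[i] <- ap[i] + eps
    am <- a; am[i] <- am[i] - eps
    lp <- compute_loss(ap, b, spec, critic = cr)$total
    lm <- compute_loss(am, b, spec, critic = cr)$total
    (lp - lm) / (2 * eps)
  }
  for (i in c(5, 100, 200)) {
    expect_equal(l$grad[i], num(i), tolerance = 1e-4)
  }
})

test_that("three epochs of L1 training reduce the training loss on a toy set", {
  psf <- fixture_psf()
  planes <- list()
  for (p in 1:2) {
    tree <- make_vessel_tree(seed = 20 + p, field_of_view = c(0.2, 0.2),
                             n_roots = 1, branching_depth = 1,
                             parallel_pair = FALSE)
    blocks <- list()
    for (b in 1:2) {
      ts <- sample_trajectories(tree, density = 50, n_frames = 4,
                                seed = 30 + 2 * p + b)
      raw <- synthesize_block(ts, psf, c(16, 16), clutter_amplitude = 20,
                              noise_sigma = 0.2, seed = 40 + 2 * p + b)
      blocks[[b]] <- svd_clutter_filter(raw, svd_filter_spec(2))
    }
    ts_ce <- sample_trajectories(tree, density = 3, n_frames = 200,
                                 seed = 50 + p, amplitude_scale = 25)
    raw <- synthesize_block(ts_ce, psf, c(16, 16), clutter_amplitude = 20,
                            noise_sigma = 0.2, seed = 60 + p)
    locs <- localize_block(svd_clutter_filter(raw, svd_filter_spec(2)), psf,
                           0.25, min_amplitude = 1.2)
    ulm <- normalize_ulm(accumulate_ulm(locs, c(16, 16), R = 2,
                                        pixel_pitch = 0.0125))
    planes[[p]] <- list(blocks = blocks, ulm = ulm)
  }
  fit <- cspd(planes,
              generator = generator_spec(in_frames = 4, n_levels = 2,
                                         base_channels = 4,
                                         n_extra_upsamples = 1, seed = 1),
              loss = loss_spec("L1"),
              config = train_config(epochs = 3, seed = 2))
  expect_s3_class(fit, "cspd")
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
  # inference contract
  img <- predict(fit, planes[[1]]$blocks[[1]])
  expect_s3_class(img, "cspd_image")
  expect_equal(dim(img$intensity), c(32L, 32L))
  expect_true(all(img$intensity >= 0 & img$intensity <= 1))
  img2 <- predict(fit, planes[[1]]$blocks[[1]])
  expect_identical(img$intensity, img2$intensity)
})
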