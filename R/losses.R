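# Training objectives: L1, L1 + lambda1 * feature-space, and
# L1 + lambda2 * adversarial (Wasserstein critic). The regularization
# weights default to lambda1 = 0.001 and lambda2 = 0.01.

#' Loss specification
#'
#' @param mode one of `"L1"`, `"L1+VGG"` (feature-space regularized) or
#'   `"L1+ADV"` (adversarially regularized).
#' @param lambda1 weight of the feature-space term (default 0.001).
#' @param lambda2 weight of the adversarial term (default 0.01).
#' @param extractor a [feature_extractor()] (built lazily when needed).
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(mode = c("L1", "L1+VGG", "L1+ADV"),
                      lambda1 = 0.001, lambda2 = 0.01,
                      extractor = NULL) {
  mode <- match.arg(mode)
  if (lambda1 < 0 || lambda2 < 0) stop_invalid("lambda weights must be >= 0")
  if (mode == "L1+VGG" && is.null(extractor)) extractor <- feature_extractor()
  structure(list(mode = mode, lambda1 = lambda1, lambda2 = lambda2,
                 extractor = extractor),
            class = "loss_spec")
}

#' Compute the training loss and its gradient
#'
#' Returns the total objective, its components, and (optionally) the
#' gradient with respect to the prediction. The L1 term is the mean
#' absolute difference; the feature term is the mean squared difference of
#' extractor feature maps; the adversarial term is minus the critic score
#' of the generated image.
#'
#' @param pred predicted image (`H x W` matrix or `(H, W, 1)` array).
#' @param target ground-truth image of the same shape (a `ulm_image`'s
#'   `intensity` or a plain matrix).
#' @param spec a [loss_spec()].
#' @param critic a `cspd_critic` (required for mode `"L1+ADV"`).
#' @param with_grad also return `grad`, the gradient w.r.t. `pred`.
#' @return list with `total`, `l1`, `feature`, `adversarial` and optionally
#'   `grad`.
#' @export
compute_loss <- function(pred, target, spec, critic = NULL, with_grad = FALSE) {
  stopifnot(inherits(spec, "loss_spec"))
  if (inherits(target, "ulm_image")) target <- target$intensity
  pred <- as_hwc(pred)
  target <- as_hwc(target)
  if (!all(dim(pred) == dim(target))) {
    stop_invalid("pred (%d x %d) and target (%d x %d) shapes differ",
                 dim(pred)[1], dim(pred)[2], dim(target)[1], dim(target)[2])
  }
  n <- length(pred)
  diff <- pred - target
  l1 <- mean(abs(diff))
  grad <- if (with_grad) array(sign(diff) / n, dim(pred)) else NULL
  feature <- 0
  adversarial <- 0
  if (spec$mode == "L1+VGG") {
    fe <- spec$extractor
    fp <- feature_forward(fe, pred, keep_cache = with_grad)
    ft <- feature_forward(fe, target)
    fd <- fp$y - ft$y
    feature <- mean(fd^2)
    if (with_grad) {
      gfeat <- feature_backward(fe, fp$caches, 2 * fd / length(fd))
      grad <- grad + spec$lambda1 * gfeat
    }
  } else if (spec$mode == "L1+ADV") {
    if (is.null(critic)) stop_invalid("mode 'L1+ADV' requires a critic")
    cf <- critic_forward(critic, pred, keep_cache = with_grad)
    adversarial <- -cf$score
    if (with_grad) {
      gadv <- critic_backward(critic, cf$caches, -1)$dx
      grad <- grad + spec$lambda2 * gadv
    }
  }
  total <- l1 +
    (if (spec$mode == "L1+VGG") spec$lambda1 * feature else 0) +
    (if (spec$mode == "L1+ADV") spec$lambda2 * adversarial else 0)
  out <- list(total = total, l1 = l1, feature = feature,
              adversarial = adversarial)
  if (with_grad) out$grad <- grad
  out
}
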