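#' Focal-loss configuration
#'
#' Class weights and focusing exponent for the focal loss
#' `FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)`, where `p_t` is the
#' predicted probability of a pixel's true class. `gamma > 0` down-weights
#' well-classified pixels — in this task, the overwhelming background — so
#' the scarce microaneurysm pixels dominate the gradient.
#'
#' @param alpha_ma weight of the microaneurysm class, in (0, 1\].
#' @param alpha_bg weight of the background class, in (0, 1\]; defaults to
#'   `1 - alpha_ma`.
#' @param gamma focusing exponent, >= 0. `gamma = 0` with unit weights
#'   reduces the loss to cross-entropy.
#' @return A `focal_config` object.
#' @export
focal_config <- function(alpha_ma = 0.25, alpha_bg = NULL, gamma = 2) {
  if (is.null(alpha_bg)) alpha_bg <- 1 - alpha_ma
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  for (a in c(alpha_ma, alpha_bg)) {
    if (!is.numeric(a) || a <= 0 || a > 1) {
      stop("class weights must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(alpha_ma = alpha_ma, alpha_bg = alpha_bg, gamma = gamma),
            class = "focal_config")
}

# p_t is clamped to [PT_CLAMP, 1] inside both losses to avoid log(0).
PT_CLAMP <- 1e-7

pt_and_alpha <- function(pred, truth, cfg) {
  stopifnot(inherits(pred, "prob_map") || (is.array(pred) && dim(pred)[3] == 2L))
  check_same_dim(pred, truth, "probability map and mask")
  t1 <- unclass(truth) == 1L
  pt <- ifelse(t1, pred[, , 2], pred[, , 1])
  list(pt = pmax(pt, PT_CLAMP),
       alpha = ifelse(t1, cfg$alpha_ma, cfg$alpha_bg))
}

#' Focal loss of a probability map against a mask
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma log(p_t)` (natural log).
#'
#' @param pred a [prob_map] spatially aligned with `truth`.
#' @param truth a [mask_image].
#' @param cfg a [focal_config()].
#' @return A nonnegative scalar.
#' @examples
#' p <- prob_map(array(c(0.1, 0.9), c(1, 1, 2)))
#' m <- mask_image(matrix(1, 1, 1))
#' focal_loss(p, m, focal_config(alpha_ma = 0.25, gamma = 2))
#' @export
focal_loss <- function(pred, truth, cfg = focal_config()) {
  pa <- pt_and_alpha(pred, truth, cfg)
  mean(-pa$alpha * (1 - pa$pt)^cfg$gamma * log(pa$pt))
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over pixels of `-log(p_t)`; identical to [focal_loss()] with
#' `gamma = 0` and unit class weights.
#'
#' @inheritParams focal_loss
#' @return A nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, truth) {
  focal_loss(pred, truth, focal_config(alpha_ma = 1, alpha_bg = 1, gamma = 0))
}

# Loss value and gradient w.r.t. logits for the training loop.
# probs: H x W x 2 softmax output; truth: mask matrix (0/1).
loss_value_grad <- function(probs, truth, cfg) {
  t1 <- unclass(truth) == 1L
  n <- length(t1)
  p1 <- probs[, , 1]; p2 <- probs[, , 2]
  pt <- pmax(ifelse(t1, p2, p1), PT_CLAMP)
  alpha <- ifelse(t1, cfg$alpha_ma, cfg$alpha_bg)
  gam <- cfg$gamma
  omp <- 1 - pt
  value <- mean(-alpha * omp^gam * log(pt))
  # d(loss_i)/d(p_t); the gamma*(1-pt)^(gamma-1) term vanishes as pt -> 1
  if (gam > 0) {
    t_focus <- ifelse(omp < 1e-12, 0, gam * omp^(gam - 1) * log(pt))
  } else {
    t_focus <- 0
  }
  dpt <- alpha * (t_focus - omp^gam / pt)
  dz1 <- dpt * pt * (ifelse(t1, 0, 1) - p1) / n
  dz2 <- dpt * pt * (ifelse(t1, 1, 0) - p2) / n
  list(value = value, dlogits = array(c(dz1, dz2), dim(probs)))
}
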