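# Training losses: the composite region loss (Dice + Focal + Boundary) on
# the refined mask, and the Dirichlet evidential digamma loss on the
# predicted concentrations. These are the pure (value-only) forms; training
# uses the differentiable tape ops, which the tests cross-check against
# these implementations.

#' Loss configuration
#'
#' @param alpha_w,beta_w,gamma_w Weights of the Dice, Focal and Boundary
#'   terms in the composite region loss. The boundary weight defaults
#'   smaller because the boundary term is signed and unbounded below on
#'   large interiors.
#' @param focal_gamma,focal_alpha Focal-loss focusing exponent and
#'   foreground class weight.
#' @param edl_weight Weight of the evidential term in the total loss.
#' @param edl_anneal_epochs Epochs over which the evidential (and
#'   boundary) weight ramps linearly from 0 (prevents early evidence
#'   collapse). `NULL` (the default) resolves to 10% of the training run's
#'   maximum epochs at fit time; standalone use of [edl_anneal()] or
#'   [total_loss()] with `NULL` falls back to 10.
#' @param kl_reg,kl_weight Optional KL-to-uniform-Dirichlet regularizer
#'   (off by default; the evidential loss used here has no KL term).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alpha_w = 1, beta_w = 1, gamma_w = 0.5,
                        focal_gamma = 2, focal_alpha = 0.25,
                        edl_weight = 1, edl_anneal_epochs = NULL,
                        kl_reg = FALSE, kl_weight = 0) {
  stopifnot(alpha_w >= 0, beta_w >= 0, gamma_w >= 0, edl_weight >= 0)
  structure(list(alpha_w = alpha_w, beta_w = beta_w, gamma_w = gamma_w,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 edl_weight = edl_weight,
                 edl_anneal_epochs = edl_anneal_epochs,
                 kl_reg = kl_reg, kl_weight = kl_weight),
            class = "loss_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1`.
#'
#' @param pred Probability map in `[0, 1]`.
#' @param target Binary map.
#' @param eps Smoothing constant.
#' @return Scalar in `[0, 1)`.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  stopifnot(all(dim(as.matrix(pred)) == dim(as.matrix(target))))
  p <- as.numeric(pred); t <- as.numeric(target)
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t`
#' the predicted probability of the true class and `alpha_t = alpha_f` for
#' foreground, `1 - alpha_f` for background. Predictions are clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param pred Foreground probability map.
#' @param target Binary map.
#' @param gamma Focusing exponent.
#' @param alpha_f Foreground class weight.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(pred, target, gamma = 2, alpha_f = 0.25) {
  p <- pmin(pmax(as.numeric(pred), 1e-7), 1 - 1e-7)
  y <- as.numeric(target) > 0.5
  pt <- ifelse(y, p, 1 - p)
  at <- ifelse(y, alpha_f, 1 - alpha_f)
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' Signed distance map of a binary mask
#'
#' Euclidean distance to the mask boundary, negative strictly inside,
#' positive outside, zero on boundary pixels (foreground pixels with a
#' 4-neighbour background).
#'
#' @param target Binary matrix.
#' @return Numeric matrix; all `+Inf` if the mask is empty.
#' @export
signed_distance_map <- function(target) {
  cpp_signed_edt(as_binary_matrix(target))
}

#' Boundary (distance-regression) loss
#'
#' Mean over pixels of `pred * phi(target)` where `phi` is the signed
#' Euclidean distance map of the target. Negative when prediction mass sits
#' inside the target, positive when it sits outside. For an empty target
#' the documented degenerate rule applies: `mean(pred) * D_max` with
#' `D_max` the image diagonal.
#'
#' @inheritParams dice_loss
#' @return Scalar (signed).
#' @export
boundary_loss <- function(pred, target) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  stopifnot(all(dim(pred) == dim(target)))
  if (sum(target > 0.5) == 0) {
    return(mean(pred) * sqrt(sum(dim(pred)^2)))
  }
  phi <- signed_distance_map(target)
  mean(pred * phi)
}

#' Composite region loss
#'
#' `alpha_w * Dice + beta_w * Focal + gamma_w * Boundary`, computed on the
#' refined mask.
#'
#' @inheritParams dice_loss
#' @param config A [loss_config()].
#' @return List with the components and the weighted sum (`liver`).
#' @export
liver_loss <- function(pred, target, config = loss_config()) {
  d <- dice_loss(pred, target)
  f <- focal_loss(pred, target, config$focal_gamma, config$focal_alpha)
  b <- boundary_loss(pred, target)
  list(dice = d, focal = f, boundary = b,
       liver = config$alpha_w * d + config$beta_w * f + config$gamma_w * b)
}

#' Dirichlet evidential (digamma) loss
#'
#' Mean over pixels of `sum_k y_k * (digamma(S) - digamma(alpha_k))`, the
#' expected cross-entropy under the predicted Dirichlet. Always >= 0, and
#' decreasing in true-class evidence.
#'
#' @param alpha Array `(H, W, K)` (or `(n, K)` matrix) of concentrations,
#'   all `>= 1`.
#' @param target Binary foreground map (foreground = class 2).
#' @return Non-negative scalar.
#' @export
edl_loss <- function(alpha, target) {
  m <- alpha_as_matrix(alpha)
  if (any(m < 1 - 1e-9)) stop("Dirichlet concentrations must all be >= 1")
  y <- as.numeric(target) > 0.5
  stopifnot(length(y) == nrow(m))
  s <- rowSums(m)
  a_true <- ifelse(y, m[, 2], m[, 1])
  mean(digamma(s) - digamma(a_true))
}

#' Evidential annealing weight
#'
#' Linear ramp from 0 to 1 over `edl_anneal_epochs` epochs (0-based epoch
#' counter; the midpoint of the ramp gives exactly 0.5).
#'
#' @param epoch 0-based epoch index.
#' @param config A [loss_config()].
#' @return Scalar in `[0, 1]`.
#' @export
edl_anneal <- function(epoch, config = loss_config()) {
  n <- config$edl_anneal_epochs %||% 10
  if (n <= 0) return(1)
  min(1, epoch / n)
}

#' Total training loss
#'
#' `liver + anneal(epoch) * edl_weight * edl`.
#'
#' @param liver Composite region loss value.
#' @param edl Evidential loss value.
#' @param epoch 0-based epoch index.
#' @param config A [loss_config()].
#' @return Scalar.
#' @export
total_loss <- function(liver, edl, epoch, config = loss_config()) {
  liver + edl_anneal(epoch, config) * config$edl_weight * edl
}

#' Full loss breakdown for one prediction
#'
#' @inheritParams dice_loss
#' @param alpha Optional Dirichlet concentrations for the evidential term.
#' @param epoch 0-based epoch index (controls the evidential anneal).
#' @param config A [loss_config()].
#' @return A one-row tibble: dice, focal, boundary, liver, edl, total.
#' @export
loss_breakdown <- function(pred, target, alpha = NULL, epoch = 0,
                           config = loss_config()) {
  lv <- liver_loss(pred, target, config)
  ed <- if (is.null(alpha)) 0 else edl_loss(alpha, target)
  tibble::tibble(dice = lv$dice, focal = lv$focal, boundary = lv$boundary,
                 liver = lv$liver, edl = ed,
                 total = total_loss(lv$liver, ed, epoch, config))
}
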