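#' Inverse-squared-area class weights
#'
#' Weights each class (background k = 1, tumor k = 2) by the inverse of the
#' squared area of that class in the ground-truth mask, so that small
#' structures are not drowned out by the background:
#' \deqn{w_k = 1 / \left(\left(\sum_n g_{kn}\right)^2 + \epsilon\right)}
#' The smoothing term keeps empty classes finite.
#'
#' @param mask binary ground-truth mask (1 = tumor) or `us_image`-paired matrix.
#' @param epsilon smoothing constant guarding empty classes.
#' @return named numeric vector `c(bg = w_1, fg = w_2)`.
#' @export
class_weights <- function(mask, epsilon = 1e-8) {
  ch <- mask_channels(mask)
  a_bg <- sum(ch$bg); a_fg <- sum(ch$fg)
  if (a_bg == 0) warning("background class is empty; its weight is 1/epsilon")
  if (a_fg == 0) warning("foreground (tumor) class is empty; its weight is 1/epsilon")
  c(bg = 1 / (a_bg^2 + epsilon), fg = 1 / (a_fg^2 + epsilon))
}

#' Generalized Dice loss
#'
#' Class-weighted Dice loss over the two-channel view of the mask:
#' \deqn{L = 1 - 2 \frac{\sum_k w_k \sum_n g_{kn} p_{kn}}
#'                      {\sum_k w_k \sum_n (g_{kn} + p_{kn})}}
#' with weights from [class_weights()]. Zero for a perfect binary prediction,
#' one for the exact complement; differentiable in the probabilities.
#'
#' @param mask binary ground-truth mask.
#' @param probs per-pixel tumor probability map in `[0, 1]`, same shape.
#' @param epsilon smoothing constant for the class weights and denominator.
#' @return scalar loss in `[0, 1]`.
#' @seealso [gw_dice_loss()] for the margin-weighted variant.
#' @export
gen_dice_loss <- function(mask, probs, epsilon = 1e-8) {
  g <- mask_channels(mask)
  p2 <- as_prob_matrix(probs)
  check_same_shape(g$fg, p2)
  p1 <- 1 - p2
  w <- suppressWarnings(class_weights(g$fg, epsilon))
  num <- w[["bg"]] * sum(g$bg * p1) + w[["fg"]] * sum(g$fg * p2)
  den <- w[["bg"]] * sum(g$bg + p1) + w[["fg"]] * sum(g$fg + p2)
  unname(1 - 2 * num / (den + epsilon))
}

# Gradient of gen_dice_loss w.r.t. the foreground probability map.
# d p1 / d p2 = -1 pointwise, so dN = w2*g2 - w1*g1 and dD = w2 - w1.
gen_dice_grad <- function(mask, probs, epsilon = 1e-8) {
  g <- mask_channels(mask)
  p2 <- as_prob_matrix(probs)
  check_same_shape(g$fg, p2)
  p1 <- 1 - p2
  w <- suppressWarnings(class_weights(g$fg, epsilon))
  num <- w[["bg"]] * sum(g$bg * p1) + w[["fg"]] * sum(g$fg * p2)
  den <- w[["bg"]] * sum(g$bg + p1) + w[["fg"]] * sum(g$fg + p2) + epsilon
  dnum <- w[["fg"]] * g$fg - w[["bg"]] * g$bg
  dden <- w[["fg"]] - w[["bg"]]
  -2 * (dnum * den - num * dden) / den^2
}

#' Gradient-weighted ground-truth mask
#'
#' Builds the per-pixel weight field that emphasizes the shallow (top) tumor
#' boundary. With `M` the set of foreground row indices and `x` a pixel's row,
#' every tumor pixel receives
#' \deqn{t(x, y) = \left(\frac{x - \max M}{\max M - \min M}\right)^2}
#' so the shallowest tumor row gets weight 1 and the deepest gets weight 0,
#' decreasing quadratically with depth. Background pixels keep the binary
#' background channel unchanged; non-tumor pixels of the foreground channel
#' are 0. The row extent is global (over the whole mask), not per column.
#'
#' A single-row tumor has `max M = min M`; the weight is then defined as 1 on
#' that row (the limit of the top-row value).
#'
#' The optional `baseline` remaps weights to `b + (1 - b) * t`, keeping the
#' same top-heavy profile but with floor `b` at the deepest row. `baseline = 0`
#' is the pure quadratic ramp; `baseline = 1` makes the field binary, which
#' reduces [gw_dice_loss()] to [gen_dice_loss()] up to its denominator.
#'
#' @param mask binary ground-truth mask with at least one tumor pixel.
#' @param baseline weight floor at the deepest tumor row, in `[0, 1]`.
#' @return matrix of foreground weights (class `gradient_weight_mask`) with
#'   attribute `tumor_row_extent = c(minM, maxM)` (1-based rows).
#' @export
gradient_weight_mask <- function(mask, baseline = 0) {
  fg <- as_mask_matrix(mask)
  if (sum(fg) == 0) stop("no tumor to weight: mask has no foreground pixels")
  if (baseline < 0 || baseline > 1) stop("baseline must lie in [0, 1]")
  rows_fg <- which(rowSums(fg) > 0)
  minM <- min(rows_fg); maxM <- max(rows_fg)
  if (maxM == minM) {
    ramp <- rep(1, nrow(fg))
  } else {
    ramp <- ((seq_len(nrow(fg)) - maxM) / (maxM - minM))^2
  }
  ramp <- baseline + (1 - baseline) * ramp
  t2 <- fg * ramp  # recycles down columns: row-wise weight
  structure(t2, class = c("gradient_weight_mask", class(t2)),
            tumor_row_extent = c(minM, maxM), baseline = baseline)
}

#' Gradient-weighted Dice loss
#'
#' Margin-aware extension of the generalized Dice loss. The foreground channel
#' of the ground truth is replaced by the gradient-weighted field `t` of
#' [gradient_weight_mask()] (background channel unchanged):
#' \deqn{L = 1 - 2 \frac{\sum_k w_k \sum_n g_{kn} t_{kn} p_{kn}}
#'                      {\sum_k w_k \sum_n (t_{kn} + p_{kn})}}
#' Missing the shallow rows of the tumor therefore costs more than missing an
#' equal area at its bottom, which targets the clinically critical top
#' (resection-surface) margin. Note the numerator masks by `g` while the
#' denominator uses `t` alone; the loss is non-negative but not exactly zero
#' for a perfect prediction unless the weight field is binary.
#'
#' @param mask binary ground-truth mask.
#' @param probs per-pixel tumor probability map, same shape.
#' @param weights optional precomputed [gradient_weight_mask()]; computed from
#'   `mask` when `NULL`.
#' @param epsilon smoothing constant.
#' @param baseline passed to [gradient_weight_mask()] when `weights` is `NULL`.
#' @return scalar loss, `>= 0`.
#' @export
gw_dice_loss <- function(mask, probs, weights = NULL, epsilon = 1e-8,
                         baseline = 0) {
  g <- mask_channels(mask)
  p2 <- as_prob_matrix(probs)
  check_same_shape(g$fg, p2)
  if (is.null(weights)) weights <- gradient_weight_mask(g$fg, baseline)
  t2 <- unclass(weights); attributes(t2) <- list(dim = dim(t2))
  check_same_shape(g$fg, t2)
  p1 <- 1 - p2
  w <- suppressWarnings(class_weights(g$fg, epsilon))
  # t1 = g1 (background channel copied unchanged), so g1*t1*p1 = g1*p1
  num <- w[["bg"]] * sum(g$bg * p1) + w[["fg"]] * sum(g$fg * t2 * p2)
  den <- w[["bg"]] * sum(g$bg + p1) + w[["fg"]] * sum(t2 + p2)
  unname(1 - 2 * num / (den + epsilon))
}

# Gradient of gw_dice_loss w.r.t. the foreground probability map.
gw_dice_grad <- function(mask, probs, weights = NULL, epsilon = 1e-8,
                         baseline = 0) {
  g <- mask_channels(mask)
  p2 <- as_prob_matrix(probs)
  check_same_shape(g$fg, p2)
  if (is.null(weights)) weights <- gradient_weight_mask(g$fg, baseline)
  t2 <- unclass(weights); attributes(t2) <- list(dim = dim(t2))
  p1 <- 1 - p2
  w <- suppressWarnings(class_weights(g$fg, epsilon))
  num <- w[["bg"]] * sum(g$bg * p1) + w[["fg"]] * sum(g$fg * t2 * p2)
  den <- w[["bg"]] * sum(g$bg + p1) + w[["fg"]] * sum(t2 + p2) + epsilon
  dnum <- w[["fg"]] * g$fg * t2 - w[["bg"]] * g$bg
  dden <- w[["fg"]] - w[["bg"]]
  -2 * (dnum * den - num * dden) / den^2
}
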