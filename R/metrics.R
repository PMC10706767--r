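#' Dice similarity coefficient
#'
#' Overlap between two binary masks, `2|A∩B| / (|A| + |B|)`. Two empty masks
#' agree perfectly on absence and score 1; exactly one empty mask scores 0.
#'
#' @param truth,pred binary masks of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(truth, pred) {
  a <- as_mask_matrix(truth, "truth"); b <- as_mask_matrix(pred, "pred")
  check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

# Topmost (shallowest) foreground row, 1-based; NA when empty.
top_tumor_row <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0) NA_integer_ else min(rows)
}

#' Tumor margin error
#'
#' Vertical distance, in millimeters, between the topmost tumor pixel of the
#' ground truth and of the prediction. The top of the image is the specimen
#' (resection) surface, so this is the error in the predicted surgical margin.
#'
#' An empty prediction has no top pixel; it is flagged and assigned the
#' worst-case error — the distance from the ground-truth top row to the image
#' bottom — so that averages over a test set remain defined.
#'
#' @param truth binary ground-truth mask with at least one tumor pixel.
#' @param pred binary predicted mask, same shape.
#' @param row_spacing_mm physical row spacing (mm/px) used for the conversion.
#' @return object of class `margin_measurement`: list with `tm_gt`, `tm_p`
#'   (1-based top rows; `tm_p` is `NA` for an empty prediction), `error_mm`,
#'   `row_spacing_mm`, and `empty_prediction`.
#' @export
tumor_margin_error <- function(truth, pred, row_spacing_mm) {
  a <- as_mask_matrix(truth, "truth"); b <- as_mask_matrix(pred, "pred")
  check_same_shape(a, b)
  if (row_spacing_mm <= 0) stop("row_spacing_mm must be positive")
  tm_gt <- top_tumor_row(a)
  if (is.na(tm_gt)) stop("ground truth has no tumor pixels")
  tm_p <- top_tumor_row(b)
  empty <- is.na(tm_p)
  error_mm <- if (empty) (nrow(a) - tm_gt) * row_spacing_mm
              else abs(tm_gt - tm_p) * row_spacing_mm
  structure(list(tm_gt = tm_gt, tm_p = tm_p, error_mm = error_mm,
                 row_spacing_mm = row_spacing_mm, empty_prediction = empty),
            class = "margin_measurement")
}

#' @export
print.margin_measurement <- function(x, ...) {
  cat(sprintf("<margin error %.3f mm (gt row %s, pred row %s, %.4f mm/px)%s>\n",
              x$error_mm, x$tm_gt, ifelse(x$empty_prediction, "none", x$tm_p),
              x$row_spacing_mm,
              if (x$empty_prediction) ", EMPTY PREDICTION" else ""))
  invisible(x)
}

#' Pixel-pooled ROC curve and AUC
#'
#' Pools the pixels of all image/probability pairs into one binary
#' classification problem and computes the receiver operating characteristic
#' and its area, as a threshold-free measure of segmentation quality.
#'
#' @param truths list of binary masks (or a single mask).
#' @param probs list of probability maps, paired with `truths`.
#' @return list with `auc` (scalar) and `curve` (data.frame with `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(truths, probs) {
  if (!is.list(truths)) truths <- list(truths)
  if (!is.list(probs)) probs <- list(probs)
  if (length(truths) != length(probs)) stop("truths and probs must be paired")
  y <- unlist(lapply(truths, function(m) as.vector(as_mask_matrix(m, "truth"))))
  p <- unlist(lapply(seq_along(probs), function(i) {
    pi <- as_prob_matrix(probs[[i]])
    check_same_shape(as_pixel_matrix(truths[[i]]), pi)
    as.vector(pi)
  }))
  if (length(unique(y)) < 2)
    stop("pooled pixels contain a single class; ROC undefined")
  r <- pROC::roc(response = y, predictor = p, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                      threshold = r$thresholds)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  list(auc = as.numeric(r$auc), curve = curve)
}

#' Dice / margin-error threshold sweep
#'
#' Binarizes probability maps at each threshold (`>=` comparator), optionally
#' post-processes the binary masks, and records mean and sd of the Dice
#' coefficient and tumor margin error across images. Exposes the trade-off
#' between the best-overlap and the best-margin operating points.
#'
#' @param truths list of binary masks.
#' @param probs paired list of probability maps.
#' @param thresholds strictly increasing values in `[0, 1]`.
#' @param row_spacing_mm row spacing for margin errors (mm/px).
#' @param postprocess apply [postprocess_mask()] to each binarized mask.
#' @return object of class `sweep_result`: data.frame with one row per
#'   threshold (`threshold`, `mean_dice`, `sd_dice`, `mean_margin_mm`,
#'   `sd_margin_mm`) and attributes `best_dice_threshold`,
#'   `best_margin_threshold`, `row_spacing_mm`.
#' @export
threshold_sweep <- function(truths, probs, thresholds, row_spacing_mm,
                            postprocess = FALSE) {
  if (!is.list(truths)) truths <- list(truths)
  if (!is.list(probs)) probs <- list(probs)
  if (length(thresholds) == 0) stop("empty threshold list")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (min(thresholds) < 0 || max(thresholds) > 1)
    stop("thresholds must lie in [0, 1]")
  res <- lapply(thresholds, function(t) {
    per <- vapply(seq_along(truths), function(i) {
      m <- (as_prob_matrix(probs[[i]]) >= t) * 1
      if (postprocess) m <- postprocess_mask(m)
      c(dice_coefficient(truths[[i]], m),
        tumor_margin_error(truths[[i]], m, row_spacing_mm)$error_mm)
    }, numeric(2))
    c(mean(per[1, ]), stats::sd(per[1, ]), mean(per[2, ]), stats::sd(per[2, ]))
  })
  res <- do.call(rbind, res)
  out <- data.frame(threshold = thresholds,
                    mean_dice = res[, 1], sd_dice = res[, 2],
                    mean_margin_mm = res[, 3], sd_margin_mm = res[, 4])
  structure(out,
            best_dice_threshold = thresholds[which.max(out$mean_dice)],
            best_margin_threshold = thresholds[which.min(out$mean_margin_mm)],
            row_spacing_mm = row_spacing_mm,
            class = c("sweep_result", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Threshold sweep over %d thresholds (%.4f mm/px)\n",
              nrow(x), attr(x, "row_spacing_mm")))
  cat(sprintf("  best Dice   %.3f at threshold %.2f\n",
              max(x$mean_dice), attr(x, "best_dice_threshold")))
  cat(sprintf("  best margin %.3f mm at threshold %.2f\n",
              min(x$mean_margin_mm), attr(x, "best_margin_threshold")))
  NextMethod()
}
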