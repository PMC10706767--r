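#' Evaluate prediction methods on a test set
#'
#' For each method (an individual model or a fusion strategy), binarizes its
#' probability maps, optionally post-processes them, and reports mean Dice,
#' mean tumor margin error (mm), and pixel-pooled AUC — one summary row per
#' method — together with per-image metrics and the predicted-vs-true margin
#' pairs with their Pearson correlation. Images with an empty prediction are
#' flagged, excluded from the correlation, and counted separately; their
#' margin error enters the mean with the worst-case convention of
#' [tumor_margin_error()]. Evaluation is a pure function of its inputs:
#' nothing is retrained or mutated.
#'
#' @param predictions named list: for each method, a list of probability
#'   maps paired with `truths`.
#' @param truths list of binary ground-truth masks.
#' @param row_spacing_mm row spacing used for all mm values; recorded in the
#'   outputs.
#' @param threshold binarization threshold (or a named vector, per method).
#' @param postprocess apply [postprocess_mask()] before computing Dice and
#'   margin error.
#' @param out_dir optional directory; writes `summary.csv`,
#'   `per_image.csv`, `margin_pairs.csv` and `summary.json`.
#' @param seed optional seed recorded in the report header (evaluation
#'   itself is deterministic).
#' @return object of class `evaluation_report`: list with `summary`,
#'   `per_image`, `margin_pairs`, `margin_correlation`, `row_spacing_mm`.
#' @export
evaluate_predictions <- function(predictions, truths, row_spacing_mm,
                                 threshold = 0.5, postprocess = TRUE,
                                 out_dir = NULL, seed = NULL) {
  if (is.null(names(predictions)) || any(names(predictions) == ""))
    stop("predictions must be a named list of methods")
  missing <- vapply(predictions, function(pm) length(pm) != length(truths),
                    logical(1))
  if (any(missing))
    stop("missing predictions for methods: ",
         paste(names(predictions)[missing], collapse = ", "))
  thr <- if (length(threshold) == 1)
    stats::setNames(rep(threshold, length(predictions)), names(predictions))
  else threshold[names(predictions)]
  summary_rows <- list(); per_image <- list(); pairs <- list()
  for (method in names(predictions)) {
    maps <- predictions[[method]]
    rows <- lapply(seq_along(truths), function(i) {
      m <- (as_prob_matrix(maps[[i]]) >= thr[[method]]) * 1
      if (postprocess) m <- postprocess_mask(m)
      me <- tumor_margin_error(truths[[i]], m, row_spacing_mm)
      data.frame(method = method, image = i,
                 dice = dice_coefficient(truths[[i]], m),
                 margin_error_mm = me$error_mm,
                 margin_gt_mm = (me$tm_gt - 1) * row_spacing_mm,
                 margin_pred_mm = if (me$empty_prediction) NA_real_
                                  else (me$tm_p - 1) * row_spacing_mm,
                 empty_prediction = me$empty_prediction,
                 threshold = thr[[method]],
                 row_spacing_mm = row_spacing_mm)
    })
    rows <- do.call(rbind, rows)
    per_image[[method]] <- rows
    auc <- roc_auc(truths, maps)$auc
    summary_rows[[method]] <- data.frame(
      method = method, mean_dice = mean(rows$dice),
      mean_margin_error_mm = mean(rows$margin_error_mm),
      auc = auc, n_images = nrow(rows),
      n_empty_predictions = sum(rows$empty_prediction),
      threshold = thr[[method]], row_spacing_mm = row_spacing_mm)
    ok <- !rows$empty_prediction
    pairs[[method]] <- rows[ok, c("method", "image", "margin_gt_mm",
                                  "margin_pred_mm")]
  }
  summary <- do.call(rbind, c(summary_rows, make.row.names = FALSE))
  per_image <- do.call(rbind, c(per_image, make.row.names = FALSE))
  margin_pairs <- do.call(rbind, c(pairs, make.row.names = FALSE))
  corr <- vapply(split(margin_pairs, margin_pairs$method), function(d) {
    if (nrow(d) < 3 || stats::sd(d$margin_gt_mm) == 0 ||
        stats::sd(d$margin_pred_mm) == 0) return(NA_real_)
    stats::cor(d$margin_gt_mm, d$margin_pred_mm)
  }, numeric(1))
  report <- structure(list(summary = summary, per_image = per_image,
                           margin_pairs = margin_pairs,
                           margin_correlation = corr,
                           row_spacing_mm = row_spacing_mm, seed = seed),
                      class = "evaluation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(per_image, file.path(out_dir, "per_image.csv"),
                     row.names = FALSE)
    utils::write.csv(margin_pairs, file.path(out_dir, "margin_pairs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, row_spacing_mm = row_spacing_mm,
           summary = summary, margin_correlation = as.list(corr)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", null = "null")
  }
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d method(s) on %d image(s), %.4f mm/px\n",
              nrow(x$summary), max(x$per_image$image), x$row_spacing_mm))
  df <- x$summary[, c("method", "mean_dice", "mean_margin_error_mm", "auc")]
  df$margin_corr <- x$margin_correlation[df$method]
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}
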