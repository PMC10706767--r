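check_map_list <- function(maps, min_n = 2) {
  if (!is.list(maps) || length(maps) < min_n)
    stop(sprintf("need at least %d probability maps", min_n))
  maps <- lapply(maps, as_prob_matrix)
  for (m in maps[-1]) check_same_shape(maps[[1]], m)
  maps
}

#' Average-fusion of probability maps
#'
#' Pixel-wise (optionally weighted) mean of several models' probability maps.
#' Weights must be non-negative and are normalized to sum to one.
#'
#' @param maps list of probability maps (same shape).
#' @param weights optional per-model weights; `NULL` gives the unweighted mean.
#' @return fused probability map in `[0, 1]`.
#' @export
fuse_average <- function(maps, weights = NULL) {
  maps <- check_map_list(maps)
  M <- length(maps)
  if (is.null(weights)) weights <- rep(1 / M, M)
  if (length(weights) != M) stop("one weight per model required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  weights <- weights / sum(weights)
  out <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
  for (i in seq_len(M)) out <- out + weights[i] * maps[[i]]
  pmin(pmax(out, 0), 1)
}

#' Vote-fusion of probability maps
#'
#' Binarizes each model's map at its threshold and labels a pixel tumor when
#' at least `vote_count` models agree. `vote_count = 1` is the union of the
#' binarized maps, `vote_count = length(maps)` their intersection.
#'
#' @param maps list of probability maps.
#' @param per_model_thresholds binarization threshold(s), recycled across
#'   models.
#' @param vote_count minimum number of agreeing models.
#' @return binary mask.
#' @export
fuse_vote <- function(maps, per_model_thresholds = 0.5, vote_count) {
  maps <- check_map_list(maps)
  M <- length(maps)
  th <- rep_len(per_model_thresholds, M)
  if (vote_count < 1 || vote_count > M)
    stop("vote_count must lie in 1..number of models")
  votes <- matrix(0L, nrow(maps[[1]]), ncol(maps[[1]]))
  for (i in seq_len(M)) votes <- votes + (maps[[i]] >= th[i])
  (votes >= vote_count) * 1
}

# Stack per-image model maps into a pooled pixel-feature matrix.
pooled_features <- function(maps_per_image) {
  M <- length(maps_per_image[[1]])
  do.call(rbind, lapply(maps_per_image, function(maps) {
    maps <- check_map_list(maps, min_n = 1)
    vapply(maps, as.vector, numeric(length(maps[[1]])))
  }))
}

#' Fit a pixel-level fusion classifier
#'
#' Trains a per-pixel classifier that maps the M models' output
#' probabilities at a pixel to a fused tumor probability. Fit on the
#' validation split only (never on test data). Logistic regression is the
#' default combiner; a small decision tree (`rpart`) is available.
#'
#' @param maps_train list over images, each a list of the M models'
#'   probability maps.
#' @param truths_train paired list of binary masks.
#' @param kind `"logistic"` or `"tree"`.
#' @param max_pixels pixel subsample cap for the fit (reproducible given
#'   `seed`).
#' @param seed subsampling seed.
#' @return object of class `ensemble_config` with `strategy = "classifier"`
#'   and fitted coefficients/model.
#' @export
fit_fusion_classifier <- function(maps_train, truths_train,
                                  kind = c("logistic", "tree"),
                                  max_pixels = 50000, seed = 1) {
  kind <- match.arg(kind)
  if (length(maps_train) != length(truths_train))
    stop("maps_train and truths_train must be paired")
  X <- pooled_features(maps_train)
  y <- unlist(lapply(truths_train, function(m) as.vector(as_mask_matrix(m))))
  if (length(unique(y)) < 2) stop("training pool contains a single class")
  if (nrow(X) > max_pixels) {
    idx <- with_local_seed(seed, sample(nrow(X), max_pixels))
    X <- X[idx, , drop = FALSE]; y <- y[idx]
    if (length(unique(y)) < 2) stop("training pool contains a single class")
  }
  colnames(X) <- paste0("m", seq_len(ncol(X)))
  df <- data.frame(y = y, X)
  if (kind == "logistic") {
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    model <- list(coef = stats::coef(fit))
  } else {
    if (!requireNamespace("rpart", quietly = TRUE))
      stop("kind = 'tree' requires the rpart package")
    model <- list(tree = rpart::rpart(factor(y) ~ ., data = df,
                                      method = "class"))
  }
  ensemble_config(strategy = "classifier", classifier = c(model, kind = kind),
                  n_models = ncol(X))
}

#' Ensemble fusion configuration
#'
#' @param strategy one of `"unweighted_avg"`, `"weighted_avg"`, `"vote"`,
#'   `"classifier"`.
#' @param model_weights per-model weights (weighted averaging).
#' @param vote_count minimum agreeing models (voting).
#' @param prob_threshold binarization threshold for fused maps.
#' @param classifier fitted pixel-classifier description.
#' @param n_models number of models fused.
#' @param criterion,criterion_value optimization provenance.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(strategy, model_weights = NULL, vote_count = NULL,
                            prob_threshold = 0.5, classifier = NULL,
                            n_models = NULL, criterion = NULL,
                            criterion_value = NULL) {
  strategy <- match.arg(strategy,
                        c("unweighted_avg", "weighted_avg", "vote", "classifier"))
  if (!is.null(model_weights)) {
    if (any(model_weights < 0)) stop("weights must be non-negative")
    model_weights <- model_weights / sum(model_weights)
  }
  structure(list(strategy = strategy, model_weights = model_weights,
                 vote_count = vote_count, prob_threshold = prob_threshold,
                 classifier = classifier, n_models = n_models,
                 criterion = criterion, criterion_value = criterion_value),
            class = "ensemble_config")
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf("<ensemble_config: %s", x$strategy))
  if (!is.null(x$model_weights))
    cat(", weights =", paste(round(x$model_weights, 2), collapse = "/"))
  if (!is.null(x$vote_count)) cat(", vote_count =", x$vote_count)
  if (!is.null(x$prob_threshold)) cat(sprintf(", threshold = %.2f", x$prob_threshold))
  if (!is.null(x$criterion))
    cat(sprintf(", %s = %.4f", x$criterion, x$criterion_value))
  cat(">\n")
  invisible(x)
}

#' Apply a fusion configuration to one image's model maps
#'
#' @param config an [ensemble_config()].
#' @param maps list of the M models' probability maps for one image.
#' @return a fused probability map (`"vote"` returns a binary mask, which is
#'   a valid probability map).
#' @export
predict_fusion <- function(config, maps) {
  switch(config$strategy,
    unweighted_avg = fuse_average(maps),
    weighted_avg = fuse_average(maps, config$model_weights),
    vote = fuse_vote(maps, config$prob_threshold %||% 0.5, config$vote_count),
    classifier = {
      cl <- config$classifier
      X <- vapply(check_map_list(maps, 1), as.vector,
                  numeric(length(maps[[1]])))
      colnames(X) <- paste0("m", seq_len(ncol(X)))
      p <- if (identical(cl$kind, "logistic")) {
        co <- cl$coef; co[is.na(co)] <- 0
        stats::plogis(co[1] + as.vector(X %*% co[-1]))
      } else {
        stats::predict(cl$tree, data.frame(X))[, "1"]
      }
      matrix(p, nrow(maps[[1]]), ncol(maps[[1]]))
    },
    stop("unknown fusion strategy"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean Dice and mean margin error of fused maps at each threshold, computed
# with O(npix + T) per image via cumulative bin counts (Dice) and the
# row-wise prefix maximum (margin).
fused_threshold_stats <- function(fmaps, truths, thresholds, row_spacing_mm) {
  Tn <- length(thresholds)
  dice <- matrix(0, length(fmaps), Tn)
  marg <- matrix(0, length(fmaps), Tn)
  for (i in seq_along(fmaps)) {
    f <- fmaps[[i]]; g <- as_mask_matrix(truths[[i]])
    H <- nrow(f)
    pos <- g == 1
    P <- sum(pos)
    # counts of pixels with value >= t, overall and among foreground
    bin_all <- findInterval(f, thresholds)        # 0..Tn
    bin_fg <- findInterval(f[pos], thresholds)
    ge_all <- rev(cumsum(rev(tabulate(bin_all + 1L, Tn + 1L))))[-1]
    ge_fg <- rev(cumsum(rev(tabulate(bin_fg + 1L, Tn + 1L))))[-1]
    dice[i, ] <- ifelse(P + ge_all == 0, 1, 2 * ge_fg / (P + ge_all))
    tm_gt <- top_tumor_row(g)
    prefmax <- cummax(apply(f, 1, max))
    for (t in seq_len(Tn)) {
      r <- which(prefmax >= thresholds[t])
      marg[i, t] <- if (length(r) == 0) (H - tm_gt) * row_spacing_mm
                    else abs(tm_gt - r[1]) * row_spacing_mm
    }
  }
  list(mean_dice = colMeans(dice), mean_margin = colMeans(marg))
}

# All weight vectors on the M-simplex with the given step.
simplex_grid <- function(M, step = 0.1) {
  n <- round(1 / step)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:n), M - 1)))
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  cbind(grid, n - rowSums(grid)) / n
}

#' Optimize a fusion strategy on validation data
#'
#' Grid search over the fusion parameters — simplex-grid model weights
#' (weighted averaging), vote counts 1..M with a shared binarization
#' threshold (voting), and/or the fused-map threshold — selecting the
#' configuration that optimizes the requested criterion on the validation
#' split. `"dice"` maximizes mean Dice, `"margin"` minimizes mean tumor
#' margin error, and `"balanced"` maximizes
#' `mean Dice - lambda * mean margin / reference margin`, scoring both terms
#' on comparable scales (the 1 mm reference is the clinical resection
#' margin). Candidates are visited in order of distance from the
#' uniform/default configuration and only a strict improvement switches, so
#' ties resolve to the most uniform choice.
#'
#' @param maps_val list over validation images, each a list of M model maps.
#' @param truths_val paired binary masks.
#' @param strategy fusion strategy to optimize.
#' @param criterion `"dice"`, `"margin"`, or `"balanced"`.
#' @param row_spacing_mm row spacing for margin errors.
#' @param lambda,ref_margin_mm balanced-criterion scalarization parameters.
#' @param weight_step simplex grid step for weighted averaging.
#' @param threshold_step fused-threshold grid step.
#' @param classifier_kind passed to [fit_fusion_classifier()].
#' @return an [ensemble_config()] carrying the achieved criterion value.
#' @export
optimize_fusion <- function(maps_val, truths_val,
                            strategy = c("unweighted_avg", "weighted_avg",
                                         "vote", "classifier"),
                            criterion = c("balanced", "dice", "margin"),
                            row_spacing_mm, lambda = 1, ref_margin_mm = 1,
                            weight_step = 0.1, threshold_step = 0.01,
                            classifier_kind = "logistic") {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  if (length(maps_val) == 0) stop("empty validation set")
  if (length(maps_val) != length(truths_val))
    stop("maps_val and truths_val must be paired")
  M <- length(maps_val[[1]])
  thresholds <- seq(threshold_step, 1 - threshold_step, by = threshold_step)
  score_of <- function(mean_dice, mean_margin) {
    switch(criterion,
           dice = mean_dice,
           margin = -mean_margin,
           balanced = mean_dice - lambda * mean_margin / ref_margin_mm)
  }
  pick_threshold <- function(fmaps) {
    st <- fused_threshold_stats(fmaps, truths_val, thresholds, row_spacing_mm)
    sc <- score_of(st$mean_dice, st$mean_margin)
    # prefer the threshold nearest 0.5 among ties
    best <- which(sc >= max(sc) - 1e-12)
    t <- best[which.min(abs(thresholds[best] - 0.5))]
    list(threshold = thresholds[t], score = sc[t])
  }
  if (strategy == "unweighted_avg") {
    fmaps <- lapply(maps_val, fuse_average)
    ch <- pick_threshold(fmaps)
    return(ensemble_config("unweighted_avg", prob_threshold = ch$threshold,
                           n_models = M, criterion = criterion,
                           criterion_value = ch$score))
  }
  if (strategy == "weighted_avg") {
    W <- simplex_grid(M, weight_step)
    ord <- order(rowSums((W - 1 / M)^2))  # uniform first; ties stay uniform
    best <- NULL
    for (r in ord) {
      w <- W[r, ]
      fmaps <- lapply(maps_val, fuse_average, weights = w)
      ch <- pick_threshold(fmaps)
      if (is.null(best) || ch$score > best$score + 1e-12)
        best <- list(w = w, threshold = ch$threshold, score = ch$score)
    }
    return(ensemble_config("weighted_avg", model_weights = best$w,
                           prob_threshold = best$threshold, n_models = M,
                           criterion = criterion, criterion_value = best$score))
  }
  if (strategy == "vote") {
    vote_thresholds <- seq(0.05, 0.95, by = max(threshold_step, 0.05))
    best <- NULL
    for (v in seq_len(M)) for (t in vote_thresholds) {
      per <- vapply(seq_along(maps_val), function(i) {
        m <- fuse_vote(maps_val[[i]], t, v)
        c(dice_coefficient(truths_val[[i]], m),
          tumor_margin_error(truths_val[[i]], m, row_spacing_mm)$error_mm)
      }, numeric(2))
      sc <- score_of(mean(per[1, ]), mean(per[2, ]))
      if (is.null(best) || sc > best$score + 1e-12)
        best <- list(v = v, t = t, score = sc)
    }
    return(ensemble_config("vote", vote_count = best$v,
                           prob_threshold = best$t, n_models = M,
                           criterion = criterion, criterion_value = best$score))
  }
  # classifier: fit on the validation pool, then choose its output threshold
  cfg <- fit_fusion_classifier(maps_val, truths_val, kind = classifier_kind)
  fmaps <- lapply(maps_val, function(maps) predict_fusion(cfg, maps))
  ch <- pick_threshold(fmaps)
  cfg$prob_threshold <- ch$threshold
  cfg$criterion <- criterion
  cfg$criterion_value <- ch$score
  cfg
}

#' Serialize / restore an ensemble configuration as JSON
#'
#' Tree classifiers are not serializable to JSON and are refused; logistic
#' coefficients round-trip exactly.
#'
#' @param config an [ensemble_config()].
#' @param path JSON file path.
#' @export
write_ensemble_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$classifier)) {
    if (!identical(x$classifier$kind, "logistic"))
      stop("only logistic classifiers serialize to JSON")
    x$classifier <- list(kind = "logistic",
                         coef = as.list(x$classifier$coef))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble_config
#' @export
read_ensemble_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$classifier)) {
    co <- unlist(x$classifier$coef)
    x$classifier <- list(coef = co, kind = "logistic")
  }
  ensemble_config(strategy = x$strategy, model_weights = x$model_weights,
                  vote_count = x$vote_count, prob_threshold = x$prob_threshold,
                  classifier = x$classifier, n_models = x$n_models,
                  criterion = x$criterion, criterion_value = x$criterion_value)
}
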