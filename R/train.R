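#' Training configuration
#'
#' @param variant one of the [model_variants()] ids (`"v1"`..`"v5"`).
#' @param loss `"gen_dice"` or `"gw_dice"`.
#' @param lr base learning rate. Fine-tuning trains at `lr / 10` (no layers
#'   are frozen: the source checkpoint acts as a weight initialization).
#' @param fine_tune start from `source_checkpoint` and apply the x0.1 rule.
#' @param source_checkpoint a checkpoint object or RDS path (required when
#'   `fine_tune = TRUE`).
#' @param batch_size,epochs training budget. Defaults are desk-scale:
#'   50 epochs from scratch, 20 when fine-tuning.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param dropout bottleneck dropout rate.
#' @param augment_data apply on-the-fly augmentation ([augment()]).
#' @param gw_baseline weight floor for the gradient-weighted mask.
#' @param seed RNG seed for the whole run (init, shuffling, augmentation).
#' @return object of class `train_config`.
#' @export
train_config <- function(variant = "v1", loss = c("gen_dice", "gw_dice"),
                         lr = 1e-3, fine_tune = FALSE,
                         source_checkpoint = NULL, batch_size = 4,
                         epochs = if (fine_tune) 20 else 50,
                         optimizer = c("adam", "sgd"), dropout = 0.1,
                         augment_data = TRUE, gw_baseline = 0, seed = 1) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  if (!variant %in% model_variants()$variant) stop("unknown model variant")
  if (lr <= 0 || batch_size < 1 || epochs < 1)
    stop("lr, batch_size, epochs must be positive")
  if (fine_tune && is.null(source_checkpoint))
    stop("fine_tune = TRUE requires a source checkpoint")
  structure(list(variant = variant, loss = loss, lr = lr,
                 fine_tune = fine_tune, source_checkpoint = source_checkpoint,
                 batch_size = batch_size, epochs = epochs,
                 optimizer = optimizer, dropout = dropout,
                 augment_data = augment_data, gw_baseline = gw_baseline,
                 seed = seed),
            class = "train_config")
}

loss_and_grad <- function(config, mask, p, gw_weights = NULL) {
  if (config$loss == "gen_dice") {
    list(loss = gen_dice_loss(mask, p), grad = gen_dice_grad(mask, p))
  } else {
    list(loss = gw_dice_loss(mask, p, weights = gw_weights),
         grad = gw_dice_grad(mask, p, weights = gw_weights))
  }
}

resolve_checkpoint <- function(x) {
  if (is.character(x)) load_checkpoint(x) else x
}

#' Train a segmentation model
#'
#' Trains one encoder-decoder variant on the training split of a phantom
#' dataset with on-the-fly augmentation, selecting the best epoch by
#' validation Dice (maximized over a coarse binarization-threshold grid,
#' no post-processing, since not every loss calibrates probabilities around
#' 0.5). With
#' `config$fine_tune`, weights are initialized from the source checkpoint and
#' the learning rate is reduced by a factor of 10; no layers are frozen.
#' Deterministic given `config$seed`.
#'
#' @param config a [train_config()].
#' @param dataset a [generate_dataset()] result (needs `train` and `val`
#'   splits).
#' @param log_csv optional path; per-epoch log written as CSV with columns
#'   `epoch`, `split`, `loss_name`, `value`.
#' @param verbose print per-epoch progress.
#' @return object of class `seg_checkpoint`: list with `net` (best-epoch
#'   weights), `config`, `history` (the log data.frame), `best_epoch`,
#'   `best_val_dice`, and `selection_threshold` (the grid threshold that
#'   achieved it).
#' @export
train <- function(config, dataset, log_csv = NULL, verbose = FALSE) {
  tr <- split_samples(dataset, "train")
  va <- split_samples(dataset, "val")
  if (length(tr) == 0 || length(va) == 0)
    stop("dataset needs non-empty train and val splits")
  vt <- model_variants()
  vrow <- vt[vt$variant == config$variant, ]
  lr <- if (config$fine_tune) config$lr * 0.1 else config$lr
  with_local_seed(config$seed, {
    net <- if (config$fine_tune) {
      resolve_checkpoint(config$source_checkpoint)$net
    } else {
      net_init(vrow$levels, vrow$base_channels,
               seed = vrow$init_seed + config$seed)
    }
    # per-sample ground-truth weight fields are reused across epochs when
    # augmentation is off; with augmentation they depend on the warped mask
    state <- if (config$optimizer == "adam") adam_init(net) else NULL
    history <- list()
    selection_thresholds <- c(0.01, 0.02, 0.05, seq(0.1, 0.9, by = 0.1))
    best <- list(dice = -Inf, epoch = NA_integer_, net = net, thr = 0.5)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample(length(tr))
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      epoch_losses <- c()
      for (b in batches) {
        grads <- NULL
        for (s in b) {
          smp <- tr[[s]]
          img <- smp$image$pixels; msk <- smp$mask
          if (config$augment_data) {
            au <- augment(img, msk)
            img <- au$image; msk <- au$mask
          }
          fwd <- net_forward(net, img, training = TRUE,
                             dropout = config$dropout, keep_cache = TRUE)
          gw <- if (config$loss == "gw_dice" && sum(msk) > 0)
            gradient_weight_mask(msk, config$gw_baseline) else NULL
          if (sum(msk) == 0) next  # augmentation pushed the tumor out of view
          lg <- loss_and_grad(config, msk, fwd$p, gw)
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite loss at epoch %d; aborting", epoch))
          epoch_losses <- c(epoch_losses, lg$loss)
          grads <- grads_add(grads, net_backward(net, fwd, lg$grad),
                             scale = 1 / length(b))
        }
        if (is.null(grads)) next
        if (config$optimizer == "adam") {
          upd <- adam_step(net, grads, state, lr)
          net <- upd$net; state <- upd$state
        } else {
          net <- sgd_step(net, grads, lr)
        }
      }
      # validation Dice maximized over a coarse threshold grid: losses such
      # as gw_dice are not calibrated around 0.5, so a fixed 0.5 selection
      # threshold would discard well-discriminating epochs
      val_probs <- lapply(va, function(smp) net_forward(net, smp$image$pixels)$p)
      grid_dice <- vapply(selection_thresholds, function(t) {
        mean(vapply(seq_along(va), function(i)
          dice_coefficient(va[[i]]$mask, (val_probs[[i]] >= t) * 1),
          numeric(1)))
      }, numeric(1))
      val_dice <- max(grid_dice)
      val_thr <- selection_thresholds[which.max(grid_dice)]
      history[[length(history) + 1]] <-
        data.frame(epoch = epoch, split = c("train", "val"),
                   loss_name = c(config$loss, "dice"),
                   value = c(mean(epoch_losses), val_dice))
      if (verbose)
        message(sprintf("epoch %d: train %s %.4f, val dice %.4f", epoch,
                        config$loss, mean(epoch_losses), val_dice))
      if (val_dice > best$dice) best <- list(dice = val_dice, epoch = epoch,
                                             net = net, thr = val_thr)
    }
    history <- do.call(rbind, history)
    if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
    structure(list(net = best$net, config = config, history = history,
                   best_epoch = best$epoch, best_val_dice = best$dice,
                   selection_threshold = best$thr),
              class = "seg_checkpoint")
  })
}

#' @export
print.seg_checkpoint <- function(x, ...) {
  cat(sprintf("<seg_checkpoint %s (%s%s), best epoch %d/%d, val dice %.3f>\n",
              x$config$variant, x$config$loss,
              if (x$config$fine_tune) ", fine-tuned" else "",
              x$best_epoch, x$config$epochs, x$best_val_dice))
  invisible(x)
}

#' Fine-tune a source-domain checkpoint
#'
#' Convenience wrapper: trains from `checkpoint` with the learning rate
#' reduced x0.1 and no frozen layers.
#'
#' @param checkpoint source-domain `seg_checkpoint` (or RDS path).
#' @param dataset target-domain dataset.
#' @param ... overrides passed to [train_config()].
#' @inheritParams train
#' @export
fine_tune <- function(checkpoint, dataset, ..., log_csv = NULL,
                      verbose = FALSE) {
  ck <- resolve_checkpoint(checkpoint)
  defaults <- list(variant = ck$config$variant, loss = ck$config$loss,
                   lr = ck$config$lr)
  args <- utils::modifyList(defaults, list(...))
  args$fine_tune <- TRUE
  args$source_checkpoint <- ck
  config <- do.call(train_config, args)
  train(config, dataset, log_csv = log_csv, verbose = verbose)
}

#' Predict probability maps
#'
#' @param checkpoint a `seg_checkpoint` (or RDS path).
#' @param images list of images (`us_image` or matrices), or a single one.
#' @return list of probability maps (matrices in `[0, 1]`), one per image,
#'   independent of batch order.
#' @export
predict_prob_map <- function(checkpoint, images) {
  ck <- resolve_checkpoint(checkpoint)
  single <- !is.list(images) || inherits(images, "us_image")
  if (single) images <- list(images)
  out <- lapply(images, function(im) net_forward(ck$net, as_pixel_matrix(im))$p)
  if (single) out[[1]] else out
}

#' Save / load a model checkpoint
#'
#' The weights are serialized with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the training configuration and best epoch for
#' provenance.
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param path RDS file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  side <- checkpoint$config
  side$source_checkpoint <- if (!is.null(side$source_checkpoint)) "inline" else NULL
  jsonlite::write_json(
    list(config = unclass(side), best_epoch = checkpoint$best_epoch,
         best_val_dice = checkpoint$best_val_dice),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Choose a model's operating threshold on validation data
#'
#' Sweeps the binarization threshold of a trained model's validation
#' probability maps and returns the operating point for the requested
#' criterion: best Dice, best tumor margin error, or their balance
#' (`mean Dice - lambda * mean margin / ref_margin_mm`). This mirrors the
#' protocol of reporting test results at a validation-chosen threshold
#' rather than a fixed 0.5.
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param dataset phantom dataset (its `val` split is used).
#' @param criterion `"balanced"`, `"dice"`, or `"margin"`.
#' @param thresholds candidate thresholds.
#' @param lambda,ref_margin_mm balanced-criterion scalarization.
#' @param postprocess post-process candidate masks during the sweep.
#' @return list with `threshold` and the sweep's `sweep_result`.
#' @export
select_operating_threshold <- function(checkpoint, dataset,
                                       criterion = c("balanced", "dice",
                                                     "margin"),
                                       thresholds = seq(0.01, 0.99, by = 0.01),
                                       lambda = 1, ref_margin_mm = 1,
                                       postprocess = FALSE) {
  criterion <- match.arg(criterion)
  va <- split_samples(dataset, "val")
  if (length(va) == 0) stop("dataset has no val split")
  sp <- va[[1]]$image$row_spacing_mm
  maps <- predict_prob_map(checkpoint, lapply(va, function(s) s$image))
  sw <- threshold_sweep(lapply(va, function(s) s$mask), maps, thresholds,
                        sp, postprocess = postprocess)
  score <- switch(criterion,
                  dice = sw$mean_dice,
                  margin = -sw$mean_margin_mm,
                  balanced = sw$mean_dice -
                    lambda * sw$mean_margin_mm / ref_margin_mm)
  list(threshold = thresholds[which.max(score)], sweep = sw)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains every cell of the grid at a (typically reduced) epoch budget and
#' ranks configurations by best validation Dice.
#'
#' @param grid named list of vectors over [train_config()] arguments, e.g.
#'   `list(lr = c(1e-2, 1e-3), batch_size = c(2, 4))`.
#' @param dataset phantom dataset with train/val splits.
#' @param ... fixed [train_config()] arguments shared by all cells.
#' @return list with `best_config` (a `train_config`), `best_checkpoint`,
#'   and `leaderboard` (data.frame, one row per cell, sorted by validation
#'   Dice).
#' @export
grid_search <- function(grid, dataset, ...) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) stop("empty grid")
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  fixed <- list(...)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    args <- utils::modifyList(fixed, as.list(cells[i, , drop = FALSE]))
    config <- do.call(train_config, args)
    ck <- tryCatch(train(config, dataset), error = function(e) e)
    if (inherits(ck, "error")) {
      # diverged cells (e.g. absurd learning rates) rank last
      results[[i]] <- list(ck = NULL,
                           row = cbind(cells[i, , drop = FALSE],
                                       val_dice = -Inf, best_epoch = NA))
    } else {
      results[[i]] <- list(ck = ck,
                           row = cbind(cells[i, , drop = FALSE],
                                       val_dice = ck$best_val_dice,
                                       best_epoch = ck$best_epoch))
    }
  }
  leaderboard <- do.call(rbind, lapply(results, `[[`, "row"))
  ord <- order(-leaderboard$val_dice)
  leaderboard <- leaderboard[ord, , drop = FALSE]
  rownames(leaderboard) <- NULL
  best <- results[[ord[1]]]
  list(best_config = best$ck$config, best_checkpoint = best$ck,
       leaderboard = leaderboard)
}
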