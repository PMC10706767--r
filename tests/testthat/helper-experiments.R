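# Desk-scale training experiments shared by the trend tests. Cached so the
# source-domain pre-training is done once per session. Problem sizes (64 x 64
# phantoms, 12-16 patients, 8-20 epochs, learning rate 3e-3 from a one-off
# grid search) are the package's desk-scale study conditions.

pretrained_source <- function(s) {
  key <- paste0("pre", s)
  if (is.null(.test_cache[[key]])) {
    src <- generate_dataset(
      phantom_spec(n_patients = 16, size = c(64, 64), domain = "source"),
      seed = 100 + s)
    .test_cache[[key]] <- train(
      train_config("v1", loss = "gen_dice", lr = 3e-3, epochs = 20,
                   seed = s, dropout = 0), src)
  }
  .test_cache[[key]]
}

test_dice <- function(ck, dataset, threshold = 0.5, postprocess = FALSE) {
  te <- marginseg:::split_samples(dataset, "test")
  mean(vapply(te, function(x) {
    m <- (predict_prob_map(ck, x$image$pixels) >= threshold) * 1
    if (postprocess) m <- postprocess_mask(m)
    dice_coefficient(x$mask, m)
  }, numeric(1)))
}

test_margin <- function(ck, dataset, threshold, postprocess = TRUE) {
  te <- marginseg:::split_samples(dataset, "test")
  sp <- te[[1]]$image$row_spacing_mm
  mean(vapply(te, function(x) {
    m <- (predict_prob_map(ck, x$image$pixels) >= threshold) * 1
    if (postprocess) m <- postprocess_mask(m)
    tumor_margin_error(x$mask, m, sp)$error_mm
  }, numeric(1)))
}
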