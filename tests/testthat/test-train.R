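test_that("network gradients match finite differences end to end", {
  set.seed(61)
  net <- marginseg:::net_init(2, 4, seed = 9)
  img <- matrix(runif(16 * 16), 16, 16)
  msk <- blob_mask(16, 16, 5:10, 4:12)
  fwd <- marginseg:::net_forward(net, img, keep_cache = TRUE)
  gr <- marginseg:::net_backward(net, fwd, marginseg:::gen_dice_grad(msk, fwd$p))
  f0 <- function(n) gen_dice_loss(msk, marginseg:::net_forward(n, img)$p)
  h <- 1e-5
  for (spot in list(c("enc", 1), c("dec", 1), c("head", NA))) {
    for (k in 1:3) {
      n2 <- net; n3 <- net
      if (spot[1] == "head") {
        n2$head$W[k] <- n2$head$W[k] + h; n3$head$W[k] <- n3$head$W[k] - h
        ana <- gr$head$W[k]
      } else {
        l <- as.integer(spot[2])
        n2[[spot[1]]][[l]]$W[k] <- n2[[spot[1]]][[l]]$W[k] + h
        n3[[spot[1]]][[l]]$W[k] <- n3[[spot[1]]][[l]]$W[k] - h
        ana <- gr[[spot[1]]][[l]]$W[k]
      }
      expect_equal(ana, (f0(n2) - f0(n3)) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("predictions are bounded, batch-order independent, and replayable", {
  ds <- cached_dataset()
  ck <- structure(list(net = marginseg:::net_init(2, 8, seed = 3),
                       config = train_config()), class = "seg_checkpoint")
  imgs <- lapply(marginseg:::split_samples(ds, "test")[1:3],
                 function(s) s$image)
  maps <- predict_prob_map(ck, imgs)
  expect_true(all(vapply(maps, function(m) min(m) >= 0 && max(m) <= 1,
                         logical(1))))
  maps_rev <- predict_prob_map(ck, rev(imgs))
  expect_identical(maps[[1]], maps_rev[[3]])
  # duplicate image in a batch gives identical maps
  dup <- predict_prob_map(ck, list(imgs[[1]], imgs[[1]]))
  expect_identical(dup[[1]], dup[[2]])
})

test_that("checkpoints round-trip through disk bit-identically", {
  ds <- cached_dataset()
  cfg <- train_config("v1", epochs = 2, lr = 3e-3, dropout = 0, seed = 5,
                      augment_data = FALSE)
  ck <- train(cfg, ds)
  img <- marginseg:::split_samples(ds, "test")[[1]]$image
  p0 <- predict_prob_map(ck, img)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_true(file.exists(paste0(path, ".json")))
  ck2 <- load_checkpoint(path)
  expect_identical(predict_prob_map(ck2, img), p0)
  # probability maps themselves persist bit-identically as float TIFF
  tf <- tempfile(fileext = ".tif")
  write_float_tiff(p0, tf)
  expect_equal(read_float_tiff(tf), p0, tolerance = 1e-7)
})

test_that("training is seeded-deterministic and the loss decreases", {
  ds <- cached_dataset()
  cfg <- train_config("v1", epochs = 2, lr = 3e-3, dropout = 0.1, seed = 7)
  a <- train(cfg, ds)
  b <- train(cfg, ds)
  expect_identical(a$history, b$history)
  tr <- a$history[a$history$split == "train", "value"]
  expect_lt(tr[2], tr[1])
  expect_no_error(train(cfg, generate_dataset(
    phantom_spec(n_patients = 3, images_per_patient = c(1, 1),
                 size = c(32, 32)), seed = 1)))
})

test_that("fine-tuning actually loads the source weights", {
  ds <- cached_dataset()
  src <- train(train_config("v1", epochs = 3, lr = 3e-3, dropout = 0,
                            seed = 9, augment_data = FALSE), ds)
  # with a vanishing learning rate the fine-tuned net stays at the source
  # weights, so its first-epoch validation Dice equals the checkpoint's
  ft <- fine_tune(src, ds, epochs = 1, lr = 1e-12, dropout = 0, seed = 9)
  v1 <- ft$history[ft$history$split == "val", "value"][1]
  expect_equal(v1, src$best_val_dice, tolerance = 1e-6)
  expect_true(ft$config$fine_tune)
  expect_error(train_config(fine_tune = TRUE), "source checkpoint")
})

test_that("grid search ranks configurations and survives absurd cells", {
  ds <- cached_dataset()
  one <- grid_search(list(lr = 3e-3), ds, variant = "v1", epochs = 2,
                     dropout = 0, seed = 3)
  expect_equal(nrow(one$leaderboard), 1)
  expect_equal(one$best_config$lr, 3e-3)

  gs <- grid_search(list(lr = c(3e-3, 1e+2)), ds, variant = "v1", epochs = 2,
                    dropout = 0, seed = 3)
  expect_equal(nrow(gs$leaderboard), 2)
  expect_equal(gs$leaderboard$lr[2], 1e+2)  # absurd cell ranks last
  expect_error(grid_search(list(), ds), "empty grid")
})
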