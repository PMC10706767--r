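test_that("average fusion is idempotent, degenerate-weight exact, and permutation-invariant", {
  set.seed(51)
  maps <- replicate(5, matrix(runif(64), 8, 8), simplify = FALSE)
  same <- replicate(3, maps[[1]], simplify = FALSE)
  expect_equal(fuse_average(same), maps[[1]])

  a <- matrix(0.2, 4, 4); b <- matrix(0.8, 4, 4)
  expect_equal(fuse_average(list(a, b)), matrix(0.5, 4, 4))

  expect_equal(fuse_average(maps, c(1, 0, 0, 0, 0)), maps[[1]])

  perm <- sample(5)
  expect_equal(fuse_average(maps), fuse_average(maps[perm]))

  expect_error(fuse_average(list(a, matrix(0.1, 3, 3))), "shape")
  expect_error(fuse_average(list(a, b), c(-1, 2)), "non-negative")
})

test_that("vote fusion spans union to intersection and matches per-pixel counting", {
  set.seed(52)
  maps <- replicate(5, matrix(runif(9), 3, 3), simplify = FALSE)
  bins <- lapply(maps, function(m) (m >= 0.5) * 1)
  union <- (Reduce(`+`, bins) >= 1) * 1
  inter <- (Reduce(`+`, bins) == 5) * 1
  expect_equal(fuse_vote(maps, 0.5, 1), union)
  expect_equal(fuse_vote(maps, 0.5, 5), inter)
  for (v in 1:5) {
    manual <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      manual[i, j] <- (sum(sapply(maps, function(m) m[i, j] >= 0.5)) >= v) * 1
    expect_equal(fuse_vote(maps, 0.5, v), manual)
  }
  expect_error(fuse_vote(maps, 0.5, 6), "vote_count")
})

test_that("vote output shrinks monotonically with the vote count", {
  set.seed(53)
  maps <- replicate(5, matrix(runif(100), 10, 10), simplify = FALSE)
  prev <- fuse_vote(maps, 0.5, 1)
  for (v in 2:5) {
    cur <- fuse_vote(maps, 0.5, v)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("the fusion classifier finds the informative model", {
  set.seed(54)
  truth <- blob_mask(16, 16, 5:12, 4:13)
  perfect <- truth * 0.98 + 0.01
  noise <- replicate(4, matrix(runif(256), 16, 16), simplify = FALSE)
  maps <- list(c(list(perfect), noise))
  cfg <- fit_fusion_classifier(maps, list(truth))
  co <- cfg$classifier$coef[-1]
  expect_equal(unname(which.max(abs(co))), 1)
  expect_gt(co[1], 0)
  # near-perfect training pixel accuracy on separable input
  fused <- predict_fusion(cfg, maps[[1]])
  expect_gt(mean((fused >= 0.5) == (truth == 1)), 0.99)
})

test_that("classifier predictions are invariant to swapping duplicate features", {
  set.seed(55)
  truth <- blob_mask(12, 12, 3:8, 3:9)
  m1 <- pmin(pmax(truth * 0.7 + matrix(runif(144), 12, 12) * 0.3, 0), 1)
  m2 <- matrix(runif(144), 12, 12)
  maps <- list(list(m1, m2, m2))
  cfg <- fit_fusion_classifier(maps, list(truth))
  swapped <- list(m1, maps[[1]][[3]], maps[[1]][[2]])
  expect_equal(predict_fusion(cfg, maps[[1]]), predict_fusion(cfg, swapped))
})

test_that("single-class training pools are rejected", {
  m <- matrix(runif(16), 4, 4)
  expect_error(fit_fusion_classifier(list(list(m, m)), list(matrix(0, 4, 4))),
               "single class")
})

test_that("weighted-average optimization concentrates weight on a perfect model", {
  set.seed(56)
  truths <- lapply(1:4, function(i) blob_mask(16, 16, (3 + i):(10 + i), 4:12))
  maps_val <- lapply(1:4, function(i) {
    good <- truths[[i]] * 0.9 + 0.05
    c(list(good), replicate(2, matrix(runif(256), 16, 16), simplify = FALSE))
  })
  cfg <- optimize_fusion(maps_val, truths, strategy = "weighted_avg",
                         criterion = "dice", row_spacing_mm = 0.1,
                         weight_step = 0.2, threshold_step = 0.05)
  expect_equal(unname(which.max(cfg$model_weights)), 1)
  expect_gte(cfg$model_weights[1], 0.6)
})

test_that("identical models tie-break to uniform weights", {
  set.seed(57)
  truths <- list(blob_mask(12, 12, 4:9, 3:10))
  m <- truths[[1]] * 0.8 + 0.1
  maps_val <- list(rep(list(m), 5))
  cfg <- optimize_fusion(maps_val, truths, strategy = "weighted_avg",
                         criterion = "dice", row_spacing_mm = 0.1,
                         weight_step = 0.2, threshold_step = 0.1)
  expect_equal(unname(cfg$model_weights), rep(1 / 5, 5))
})

test_that("dice and margin criteria select different thresholds on the trade-off fixture", {
  fx <- tradeoff_fixture(n = 4, seed = 8)
  maps_val <- lapply(fx$probs, function(p) list(p, p))
  cfg_d <- optimize_fusion(maps_val, fx$truths, strategy = "unweighted_avg",
                           criterion = "dice", row_spacing_mm = 15 / 64,
                           threshold_step = 0.02)
  cfg_m <- optimize_fusion(maps_val, fx$truths, strategy = "unweighted_avg",
                           criterion = "margin", row_spacing_mm = 15 / 64,
                           threshold_step = 0.02)
  expect_lt(cfg_m$prob_threshold, cfg_d$prob_threshold)
})

test_that("ensemble configs round-trip through JSON", {
  cfg <- ensemble_config("weighted_avg", model_weights = c(2, 1, 1),
                         prob_threshold = 0.42, n_models = 3,
                         criterion = "dice", criterion_value = 0.9)
  path <- tempfile(fileext = ".json")
  write_ensemble_config(cfg, path)
  back <- read_ensemble_config(path)
  expect_equal(back$model_weights, cfg$model_weights)
  expect_equal(back$prob_threshold, 0.42)
  expect_equal(back$strategy, "weighted_avg")

  set.seed(58)
  truth <- blob_mask(10, 10, 3:7, 3:7)
  maps <- list(list(truth * 0.9 + 0.05, matrix(runif(100), 10, 10)))
  clf <- fit_fusion_classifier(maps, list(truth))
  write_ensemble_config(clf, path)
  clf2 <- read_ensemble_config(path)
  expect_equal(predict_fusion(clf2, maps[[1]]), predict_fusion(clf, maps[[1]]),
               tolerance = 1e-12)
})
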