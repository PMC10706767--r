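test_that("Dice coefficient handles overlap, identity, and empties", {
  a <- blob_mask(20, 20, 1:10, 1:10)          # 100 px
  b <- blob_mask(20, 20, 1:10, 1:5)           # 50 px, all inside a
  expect_equal(dice_coefficient(a, b), 2 * 50 / 150, tolerance = 1e-12)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(blob_mask(8, 8, 1:2, 1:2),
                                blob_mask(8, 8, 5:6, 5:6)), 0)
  expect_equal(dice_coefficient(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_equal(dice_coefficient(a, matrix(0, 20, 20)), 0)
  expect_error(dice_coefficient(a, matrix(0, 4, 4)), "shape")
})

test_that("Dice is symmetric and flip-invariant", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_mask(12, 12); b <- random_mask(12, 12)
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_equal(dice_coefficient(a[12:1, ], b[12:1, ]),
                 dice_coefficient(a, b))
  }
})

test_that("tumor margin error measures the top-pixel distance in mm", {
  gt <- blob_mask(30, 20, 10:20, 5:15)
  pr <- blob_mask(30, 20, 14:20, 5:15)
  me <- tumor_margin_error(gt, pr, 0.1)
  expect_equal(me$error_mm, 0.4, tolerance = 1e-12)
  expect_equal(me$tm_gt, 10); expect_equal(me$tm_p, 14)

  expect_equal(tumor_margin_error(gt, gt, 0.1)$error_mm, 0)

  up <- blob_mask(30, 20, 7:20, 5:15)    # 3 rows shallower
  dn <- blob_mask(30, 20, 13:20, 5:15)   # 3 rows deeper
  expect_equal(tumor_margin_error(gt, up, 0.1)$error_mm,
               tumor_margin_error(gt, dn, 0.1)$error_mm)

  expect_error(tumor_margin_error(matrix(0, 5, 5), blob_mask(5, 5, 2, 2), 0.1),
               "no tumor")
})

test_that("empty predictions get the flagged worst-case margin", {
  gt <- blob_mask(30, 20, 10:20, 5:15)
  me <- tumor_margin_error(gt, matrix(0, 30, 20), 0.1)
  expect_true(me$empty_prediction)
  expect_equal(me$error_mm, (30 - 10) * 0.1)
})

test_that("margin error is invariant to horizontal shifts and additive in vertical ones", {
  gt <- blob_mask(30, 30, 10:18, 10:20)
  sh <- blob_mask(30, 30, 10:18, 13:23)   # horizontal translation
  expect_equal(tumor_margin_error(gt, sh, 0.2)$error_mm, 0)
  for (k in 1:4) {
    dn <- blob_mask(30, 30, (10 + k):18, 10:20)
    expect_equal(tumor_margin_error(gt, dn, 0.2)$error_mm, k * 0.2)
  }
})

test_that("pixel-pooled AUC matches the pair-counting oracle", {
  gt <- blob_mask(8, 8, 3:5, 3:5)
  expect_equal(roc_auc(gt, gt * 0.999 + 0.0005)$auc, 1)
  expect_equal(roc_auc(gt, 1 - (gt * 0.999 + 0.0005))$auc, 0)
  expect_error(roc_auc(matrix(0, 4, 4), matrix(runif(16), 4, 4)),
               "single class")

  set.seed(22)
  for (i in 1:10) {
    y <- matrix(rbinom(20, 1, 0.4), 4, 5)
    if (length(unique(as.vector(y))) < 2) next
    p <- matrix(round(runif(20), 2), 4, 5)  # rounded: exercises ties
    expect_equal(roc_auc(y, p)$auc,
                 oracle_auc_pairs(as.vector(y), as.vector(p)),
                 tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(23)
  y <- list(random_mask(10, 10), random_mask(10, 10))
  p <- list(matrix(runif(100), 10, 10), matrix(runif(100), 10, 10))
  a0 <- roc_auc(y, p)$auc
  expect_equal(roc_auc(y, lapply(p, function(m) m^3))$auc, a0)
  expect_equal(roc_auc(y, lapply(p, stats::plogis))$auc, a0)
})

test_that("threshold sweep matches a manual per-threshold evaluation", {
  gt <- blob_mask(8, 8, 3:6, 2:7)
  p <- matrix(0, 8, 8)
  p[3:6, 2:7] <- 0.6
  p[2, 2:7] <- 0.3       # faint halo one row above the tumor
  p[7:8, 4] <- 0.8       # a confident spur below
  sw <- threshold_sweep(list(gt), list(p), c(0.25, 0.5, 0.75), 0.1)
  for (i in 1:3) {
    m <- (p >= c(0.25, 0.5, 0.75)[i]) * 1
    expect_equal(sw$mean_dice[i], dice_coefficient(gt, m))
    expect_equal(sw$mean_margin_mm[i],
                 tumor_margin_error(gt, m, 0.1)$error_mm)
  }
  expect_error(threshold_sweep(list(gt), list(p), numeric(0), 0.1), "empty")
  expect_error(threshold_sweep(list(gt), list(p), c(0.5, 0.2), 0.1),
               "increasing")
})

test_that("perfect probability maps sweep to constant optimal curves", {
  gt <- blob_mask(16, 16, 5:10, 4:12)
  sw <- threshold_sweep(list(gt, gt), list(gt, gt),
                        seq(0.1, 0.9, by = 0.2), 0.1)
  expect_true(all(sw$mean_dice == 1))
  expect_true(all(sw$mean_margin_mm == 0))
})

test_that("the trade-off fixture separates Dice- and margin-optimal thresholds", {
  fx <- tradeoff_fixture(n = 4, seed = 7)
  sw <- threshold_sweep(fx$truths, fx$probs, seq(0.05, 0.95, by = 0.05),
                        row_spacing_mm = 15 / 64)
  t_dice <- attr(sw, "best_dice_threshold")
  t_marg <- attr(sw, "best_margin_threshold")
  expect_false(isTRUE(all.equal(t_dice, t_marg)))
  expect_lt(t_marg, t_dice)  # the faint top halo is recovered at low thresholds
})
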