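test_that("class weights follow the inverse-squared-area rule", {
  m <- blob_mask(4, 4, 2:3, 2:3)  # 4 tumor px, 12 background px
  w <- class_weights(m)
  expect_equal(unname(w["fg"]), 1 / 16, tolerance = 1e-6)
  expect_equal(unname(w["bg"]), 1 / 144, tolerance = 1e-6)

  expect_warning(w0 <- class_weights(matrix(0, 4, 4)), "foreground")
  expect_true(is.finite(w0["fg"]) && w0["fg"] > 1e6)

  m_eq <- blob_mask(4, 4, 1:2, 1:4)  # 8 px each class
  w_eq <- class_weights(m_eq)
  expect_equal(unname(w_eq["fg"]), unname(w_eq["bg"]))
})

test_that("generalized Dice loss hits its exact endpoints", {
  m <- blob_mask(6, 6, 2:4, 3:5)
  expect_equal(gen_dice_loss(m, m), 0, tolerance = 1e-7)
  expect_equal(gen_dice_loss(m, 1 - m), 1, tolerance = 1e-7)
  expect_error(gen_dice_loss(m, matrix(0.5, 4, 4)), "shape")
})

test_that("both losses match scalar-loop oracles on random instances", {
  set.seed(11)
  for (i in 1:25) {
    m <- random_mask(8, 8)
    p <- matrix(runif(64), 8, 8)
    expect_equal(gen_dice_loss(m, p), oracle_gen_dice(m, p), tolerance = 1e-6)
    expect_equal(gw_dice_loss(m, p), oracle_gw_dice(m, p), tolerance = 1e-6)
  }
})

test_that("gradient weight mask implements the quadratic depth ramp", {
  m <- blob_mask(8, 8, 2:6, 2:7)  # tumor rows 2..6
  t2 <- gradient_weight_mask(m)
  expect_equal(t2[2, 2], 1.0)
  expect_equal(t2[4, 2], 0.25)
  expect_equal(t2[6, 2], 0.0)
  expect_equal(attr(t2, "tumor_row_extent"), c(2, 6))
  expect_true(all(t2[m == 0] == 0))

  # weight is non-increasing with depth within any column of the tumor
  for (cc in 2:7) expect_true(all(diff(t2[2:6, cc]) <= 0))

  single <- blob_mask(8, 8, 4, 2:5)
  expect_true(all(gradient_weight_mask(single)[single == 1] == 1))

  expect_error(gradient_weight_mask(matrix(0, 4, 4)), "no tumor")

  set.seed(12)
  for (i in 1:20) {
    m <- random_mask(9, 7)
    expect_equal(as.vector(gradient_weight_mask(m)),
                 as.vector(oracle_gw_mask(m)))
  }
})

test_that("baseline variant spans the pseudocode and prose profiles", {
  m <- blob_mask(10, 6, 3:8, 2:5)
  t0 <- gradient_weight_mask(m, baseline = 0)
  expect_equal(range(t0[m == 1]), c(0, 1))
  # baseline 0.5 scaled x2 gives the 2 -> 1 top-to-bottom prose profile
  t5 <- gradient_weight_mask(m, baseline = 0.5)
  expect_equal(range(2 * t5[m == 1]), c(1, 2))
  # baseline 1 makes the field binary and reduces GWDice to GenDice
  t1 <- gradient_weight_mask(m, baseline = 1)
  expect_equal(as.vector(t1), as.vector(m))
})

test_that("GWDice with uniform weights reduces to GenDice", {
  set.seed(13)
  for (i in 1:10) {
    m <- random_mask(8, 8)
    p <- matrix(runif(64), 8, 8)
    expect_equal(gw_dice_loss(m, p, baseline = 1), gen_dice_loss(m, p),
                 tolerance = 1e-9)
  }
  m <- blob_mask(8, 8, 3:6, 3:6)
  expect_equal(gw_dice_loss(m, m, baseline = 1), 0, tolerance = 1e-7)
})

test_that("missing the tumor top costs more than missing the bottom", {
  m <- blob_mask(16, 16, 4:13, 3:14)
  k <- ceiling(0.2 * sum(m))
  p_top <- erase_band(m, k, "top")
  p_bot <- erase_band(m, k, "bottom")
  expect_equal(dice_coefficient(m, p_top), dice_coefficient(m, p_bot))
  expect_gt(gw_dice_loss(m, p_top), gw_dice_loss(m, p_bot))
  expect_equal(gen_dice_loss(m, p_top), gen_dice_loss(m, p_bot),
               tolerance = 1e-9)
})

test_that("analytic loss gradients match finite differences", {
  set.seed(14)
  for (i in 1:5) {
    m <- random_mask(6, 6)
    p <- matrix(runif(36, 0.05, 0.95), 6, 6)
    h <- 1e-4
    for (fn in list(c(gen_dice_loss, marginseg:::gen_dice_grad),
                    c(gw_dice_loss, marginseg:::gw_dice_grad))) {
      loss <- fn[[1]]; grad <- fn[[2]]
      g <- grad(m, p)
      idx <- sample(36, 6)
      for (j in idx) {
        p2 <- p; p2[j] <- p[j] + h
        p3 <- p; p3[j] <- p[j] - h
        expect_equal(g[j], (loss(m, p2) - loss(m, p3)) / (2 * h),
                     tolerance = 1e-3)
      }
    }
  }
})
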