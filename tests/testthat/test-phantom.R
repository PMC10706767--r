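test_that("phantoms are deterministic given a seed", {
  sp <- phantom_spec(size = c(64, 64))
  a <- generate_phantom(sp, seed = 7)
  b <- generate_phantom(sp, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(sp, seed = 8)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("the mask top row realizes the sampled margin depth", {
  sp <- phantom_spec(size = c(64, 64))
  for (s in 1:20) {
    ph <- generate_phantom(sp, seed = 100 + s)
    expected_top <- ph$meta$margin_mm / sp$row_spacing_mm
    expect_lte(abs((ph$meta$top_row - 1) - expected_top), 1)
    expect_equal(marginseg:::top_tumor_row(ph$mask), ph$meta$top_row)
  }
})

test_that("lesions are hypoechoic and images well-formed", {
  sp <- phantom_spec(size = c(64, 64))
  for (s in 1:10) {
    ph <- generate_phantom(sp, seed = 200 + s)
    px <- ph$image$pixels
    expect_true(min(px) >= 0 && max(px) <= 1)
    expect_true(all(ph$mask %in% c(0, 1)))
    expect_gt(sum(ph$mask), 0)
    expect_lt(mean(px[ph$mask == 1]), mean(px[ph$mask == 0]))
  }
})

test_that("datasets split patient-wise with reproducible manifests", {
  sp <- phantom_spec(n_patients = 20, size = c(32, 32))
  ds <- generate_dataset(sp, seed = 3)
  man <- ds$manifest
  expect_setequal(unique(man$split), c("train", "val", "test"))
  # no patient spans splits
  per_patient <- tapply(man$split, man$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
  expect_true(all(table(man$patient_id) >= 1 & table(man$patient_id) <= 3))
  # proportions approximate the configured fractions
  expect_gt(mean(man$split == "train"), 0.5)

  ds2 <- generate_dataset(sp, seed = 3)
  expect_identical(ds2$manifest, man)
  expect_error(generate_dataset(phantom_spec(n_patients = 2), seed = 1),
               "too few")
})

test_that("one image per patient means one row per patient", {
  sp <- phantom_spec(n_patients = 10, images_per_patient = c(1, 1),
                     size = c(32, 32))
  ds <- generate_dataset(sp, seed = 4)
  expect_equal(nrow(ds$manifest), 10)
  expect_equal(length(unique(ds$manifest$patient_id)), 10)
})

test_that("generated margins recover the cohort distribution", {
  sp <- phantom_spec(size = c(64, 64))
  margins <- vapply(1:300, function(i) {
    ph <- generate_phantom(sp, seed = 5000 + i)
    (ph$meta$top_row - 1) * sp$row_spacing_mm
  }, numeric(1))
  expect_lt(abs(mean(margins) - 6.4) / 6.4, 0.10)
  expect_lt(abs(stats::sd(margins) - 3.7) / 3.7, 0.10)
})

test_that("source and target domains differ in speckle statistics", {
  hp_var <- function(ph) {
    px <- ph$image$pixels
    r <- px - as.matrix(EBImage::gblur(px, 2))
    stats::var(r[ph$mask == 0])
  }
  src <- vapply(1:15, function(i)
    hp_var(generate_phantom(phantom_spec(size = c(64, 64), domain = "source"),
                            seed = i)), numeric(1))
  tgt <- vapply(1:15, function(i)
    hp_var(generate_phantom(phantom_spec(size = c(64, 64), domain = "target"),
                            seed = i)), numeric(1))
  expect_lt(stats::wilcox.test(src, tgt)$p.value, 1e-4)
  expect_lt(mean(src), mean(tgt))
})

test_that("raw-scale phantoms exercise the crop/resize path", {
  sp <- phantom_spec(raw = TRUE)
  ph <- generate_phantom(sp, seed = 11)
  expect_equal(dim(ph$image$pixels), c(344L, 430L))
  expect_equal(ph$image$row_spacing_mm, 30 / 344, tolerance = 1e-12)
  cr <- crop_top_half(ph$image, ph$mask)
  expect_equal(nrow(cr$image$pixels), 172)
  rz <- resize_and_normalize(cr$image, cr$mask, target = c(128, 128))
  expect_equal(dim(rz$image$pixels), c(128L, 128L))
  expect_equal(rz$image$row_spacing_mm, (30 / 344) * 172 / 128,
               tolerance = 1e-12)
})
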