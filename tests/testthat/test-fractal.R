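test_that("default box-size series is 5..575 step 3, 191 sizes", {
  bs <- defaultBoxSizes()
  expect_length(bs, 191L)
  expect_identical(bs[1:3], c(5L, 8L, 11L))
  expect_identical(bs[191], 575L)
})

test_that("grid scan matches the naive per-box oracle exactly", {
  set.seed(31)
  px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  for (counting in c("binary", "differential")) {
    for (off in list(c(0L, 0L), c(2L, 3L))) {
      sc <- scanGrid(greyImage(px), offset = off, boxSizes = c(3L, 5L, 7L),
        counting = counting)
      for (k in seq_along(sc$boxSizes)) {
        o <- naiveBoxScan(px, sc$boxSizes[k], off[1], off[2], counting)
        expect_equal(sc$N[k], o$Ncorr)
        expect_equal(sc$massMean[k], o$massMean)
        expect_equal(sc$massSD[k], o$massSD)
      }
    }
  }
})

test_that("constant image: all dimensions 2, lacunarity and grid SD zero", {
  bs <- defaultBoxSizes()
  ff <- fractalFeatures(greyImage(matrix(100L, 150, 150)),
    boxSizes = bs[bs <= 140])
  expect_equal(unname(ff["d_b"]), 2, tolerance = 0.01)
  expect_equal(unname(ff["d_b_min"]), unname(ff["d_b_max"]), tolerance = 1e-9)
  expect_equal(unname(ff["d_m"]), 2, tolerance = 0.01)
  expect_equal(unname(ff["d_x_best_r2"]), 2, tolerance = 0.01)
  expect_equal(unname(ff["sd_d_b"]), 0, tolerance = 1e-9)
  for (nm in c("lam", "lam_prime", "lam_min", "lam_max", "cv_lam_g",
    "cv_lam_prime_g"))
    expect_equal(unname(ff[nm]), 0, tolerance = 1e-12)
})

test_that("feature vector has exactly the 23 canonical names", {
  ff <- fractalFeatures(greyImage(matrix(100L, 64, 64)), nGrids = 3,
    boxSizes = c(5L, 8L, 11L, 14L, 17L))
  expect_length(ff, 23L)
  expect_identical(names(ff), fractalFeatureNames())
})

test_that("fixed seed reproduces the features bit for bit", {
  img <- generateImage(nestImageSpec(width = 96L, height = 96L,
    nestCount = 8L, seed = 14))
  bs <- c(5L, 8L, 11L, 17L, 23L, 29L)
  f1 <- fractalFeatures(img, nGrids = 6, boxSizes = bs, seed = 3)
  f2 <- fractalFeatures(img, nGrids = 6, boxSizes = bs, seed = 3)
  f3 <- fractalFeatures(img, nGrids = 6, boxSizes = bs, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("lacunarity grows when mass is concentrated at equal total mass", {
  # one dark blob vs the same number of dark pixels spread uniformly
  W <- 120L
  blob <- matrix(255L, W, W)
  blob[31:60, 31:60] <- 0L                    # 900 dark pixels in one block
  set.seed(33)
  spread <- matrix(255L, W, W)
  spread[sample.int(W * W, 900L)] <- 0L       # 900 dark pixels scattered
  bs <- defaultBoxSizes(); bs <- bs[bs <= 100]
  fb <- fractalFeatures(greyImage(blob), boxSizes = bs, seed = 5)
  fs <- fractalFeatures(greyImage(spread), boxSizes = bs, seed = 5)
  expect_gt(fb[["lam_prime"]], fs[["lam_prime"]])
  expect_gt(fb[["lam"]], fs[["lam"]])
})

test_that("empty stained support yields NA features, not an error", {
  s <- sliceImage(greyImage(matrix(170L, 64, 64)), intensityRange(220, 240))
  ff <- fractalFeatures(s, nGrids = 3, boxSizes = c(5L, 8L, 11L, 14L))
  expect_true(all(is.na(ff)))
})

test_that("too-small images and too-few sizes error", {
  expect_error(scanGrid(greyImage(matrix(1L, 4, 4)), boxSizes = c(5L, 8L)),
    "smaller")
  expect_error(fractalFeatures(greyImage(matrix(1L, 10, 10)),
    boxSizes = c(5L, 8L)), "fewer than 3")
})
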