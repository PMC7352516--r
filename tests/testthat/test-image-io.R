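test_that("PNG and TIFF round-trip losslessly at 8 bits", {
  set.seed(4)
  img <- greyImage(matrix(sample(0:255, 300, replace = TRUE), 20, 15))
  for (ext in c("png", "tiff")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeGreyImage(img, f)
    back <- readGreyImage(f)
    expect_s4_class(back, "GreyImage")
    expect_identical(pixels(back), pixels(img))
  }
})

test_that("constant grey PNG loads as constant GreyImage", {
  f <- withr::local_tempfile(fileext = ".png")
  writeGreyImage(greyImage(matrix(200L, 10, 10)), f)
  img <- readGreyImage(f)
  expect_true(all(pixels(img) == 200L))
})

test_that("RGB input is flagged for decomposition, 16-bit is rejected", {
  f <- withr::local_tempfile(fileext = ".tiff")
  arr <- array(runif(4 * 5 * 3), dim = c(5, 4, 3))
  tiff::writeTIFF(arr, f, bits.per.sample = 8L)
  rgb <- readGreyImage(f)
  expect_s3_class(rgb, "rgb_raster")
  expect_equal(dim(rgb), c(4L, 5L, 3L))

  f16 <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(matrix(runif(20), 4, 5), f16, bits.per.sample = 16L)
  expect_error(readGreyImage(f16), "bit depth")
})

test_that("pure white decomposes to no stain in both channels", {
  arr <- array(255L, dim = c(6, 6, 3))
  class(arr) <- "rgb_raster"
  ch <- decomposeStains(arr)
  expect_true(all(pixels(ch$blue) == 255L))
  expect_true(all(pixels(ch$brown) == 255L))
})

test_that("deconvolution inverts forward Beer-Lambert mixing within 1 grey level", {
  set.seed(11)
  d1 <- runif(60, 0, 0.8)  # non-saturated densities
  d2 <- runif(60, 0, 0.8)
  ch <- decomposeStains(mixStains(d1, d2))
  expect_true(max(abs(as.numeric(pixels(ch$blue)) - 255 * 10^(-d1))) <= 1)
  expect_true(max(abs(as.numeric(pixels(ch$brown)) - 255 * 10^(-d2))) <= 1)
  # with 8-bit forward quantisation the recovery degrades gracefully
  chq <- decomposeStains(mixStains(d1, d2, quantize = TRUE))
  expect_true(max(abs(as.numeric(pixels(chq$blue)) - 255 * 10^(-d1))) <= 3)
})

test_that("a single-stain image leaves the other channel essentially empty", {
  set.seed(12)
  ch <- decomposeStains(mixStains(runif(50, 0, 0.6), rep(0, 50),
    quantize = TRUE))
  expect_true(all(pixels(ch$brown) >= 254L))
})

test_that("collinear stain vectors are rejected", {
  s <- rbind(c(1, 0, 0), c(2, 0, 0))
  arr <- array(128L, dim = c(3, 3, 3))
  expect_error(decomposeStains(arr, stains = s), "collinear")
})

test_that("histogram counts are conserved on any input", {
  expect_identical(unname(intensityHistogram(greyImage(matrix(170L, 10, 10)))[171]),
    100L)
  img1 <- greyImage(matrix(0:255, 16, 16))
  expect_true(all(intensityHistogram(img1) == 1L))
  img2 <- generateImage(nestImageSpec(width = 64L, height = 64L,
    nestCount = 5L, seed = 3))
  expect_identical(sum(intensityHistogram(img2)), 64L * 64L)
})

test_that("GreyImage validity rejects out-of-range and empty rasters", {
  expect_error(greyImage(matrix(300L, 2, 2)))
  expect_error(greyImage(matrix(-1L, 2, 2)))
  expect_error(greyImage(matrix(2.5, 2, 2)))
})
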