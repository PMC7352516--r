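test_that("macro boundary semantics: both boundary levels whitened", {
  img <- greyImage(matrix(c(100L, 160L, 170L, 180L), 2, 2))
  s <- sliceImage(img, intensityRange(160, 180))
  expect_identical(sum(keptMask(s)), 1L)          # only the 170
  expect_true(keptMask(s)[1, 2])
  expect_identical(pixels(s)[!keptMask(s)], rep(255L, 3))
})

test_that("lo = 0 keeps level 0 but whitens the upper boundary", {
  img <- greyImage(matrix(c(0L, 129L, 130L, 255L), 2, 2))
  s <- sliceImage(img, intensityRange(0, 130))
  expect_identical(sort(pixels(img)[keptMask(s)]), c(0L, 129L))
})

test_that("worked 3x3 example keeps exactly the 170 pixel", {
  s <- sliceImage(workedImage(), intensityRange(160, 180))
  expect_identical(sum(keptMask(s)), 1L)
  expect_identical(pixels(workedImage())[keptMask(s)], 170L)
  m <- binaryMask(s)
  expect_identical(sum(m == 255L), 1L)
  expect_identical(which(m == 255L), which(keptMask(s)))
})

test_that("inclusive-lower mode keeps the lower boundary instead", {
  img <- greyImage(matrix(c(160L, 180L), 1, 2))
  sm <- sliceImage(img, intensityRange(160, 180), boundary = "macro")
  si <- sliceImage(img, intensityRange(160, 180), boundary = "inclusive-lower")
  expect_identical(sum(keptMask(sm)), 0L)
  expect_identical(pixels(img)[keptMask(si)], 160L)
})

test_that("default seven ranges partition all non-boundary levels below 255", {
  img <- greyImage(matrix(0:255, 16, 16))
  slices <- sliceAll(img)
  expect_length(slices, 7L)
  counts <- vapply(slices, function(s) sum(keptMask(s)), integer(1))
  expect_identical(sum(counts), 256L - 6L - 1L)   # 249
  membership <- Reduce(`+`, lapply(slices, keptMask))
  boundary <- pixels(img) %in% c(130L, 160L, 180L, 200L, 220L, 240L, 255L)
  expect_true(all(membership[!boundary] == 1L))
  expect_true(all(membership[boundary] == 0L))
})

test_that("slicing conservation: kept + boundary + white = total", {
  img <- generateImage(nestImageSpec(width = 64L, height = 64L, seed = 5,
    nestCount = 6L))
  kept <- sum(vapply(sliceAll(img), function(s) sum(keptMask(s)), integer(1)))
  h <- intensityHistogram(img)
  boundary <- sum(h[as.character(c(130, 160, 180, 200, 220, 240))])
  white <- h["255"]
  expect_equal(kept + boundary + white, sum(h), ignore_attr = TRUE)
})

test_that("slicing a slice by its own range changes nothing", {
  img <- generateImage(nestImageSpec(width = 64L, height = 64L, seed = 9,
    nestCount = 6L))
  s1 <- sliceImage(img, intensityRange(160, 180))
  s2 <- sliceImage(s1@image, intensityRange(160, 180))
  expect_identical(pixels(s2), pixels(s1))
  expect_identical(keptMask(s2), keptMask(s1))
})

test_that("single 0-255 range keeps everything below white", {
  img <- greyImage(matrix(c(0L, 100L, 254L, 255L), 2, 2))
  s <- sliceImage(img, intensityRange(0, 255))
  expect_identical(keptMask(s), pixels(img) < 255L)
  expect_identical(pixels(s), pixels(img)) # 255 maps to 255: identity
})

test_that("range shares: constant image and enumerated levels", {
  sh <- rangeShare(greyImage(matrix(170L, 5, 5)))
  expect_equal(unname(sh["160-180"]), 1)
  expect_equal(sum(sh), 1)
  sh2 <- rangeShare(greyImage(matrix(0:255, 16, 16)))
  # open-interval widths over 256 levels, lo=0 exception included
  expect_equal(unname(sh2), c(130, 29, 19, 19, 19, 19, 14) / 256)
})

test_that("overlapping non-boundary-sharing ranges warn", {
  img <- greyImage(matrix(100L, 4, 4))
  expect_warning(
    sliceAll(img, list(intensityRange(0, 150), intensityRange(120, 200))),
    "overlap")
})

test_that("overlay paints kept pixels pure red and leaves the rest grey", {
  img <- workedImage()
  s <- sliceImage(img, intensityRange(160, 180))
  ov <- overlayImage(img, s)
  kp <- which(keptMask(s))
  expect_identical(ov[, , 1][kp], 255L)
  expect_identical(ov[, , 2][kp], 0L)
  expect_identical(ov[, , 1][-kp], pixels(img)[-kp])
  # empty slice: overlay equals the replicated original
  s0 <- sliceImage(greyImage(matrix(255L, 3, 3)), intensityRange(160, 180))
  expect_identical(sum(keptMask(s0)), 0L)
  expect_true(all(binaryMask(s0) == 0L))
})
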