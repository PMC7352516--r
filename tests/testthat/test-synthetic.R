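test_that("degenerate single-value mixes give exactly two grey levels", {
  spec <- nestImageSpec(width = 64L, height = 64L, nestCount = 6L,
    nestIntensityMix = intensityMix(100L, 100L, 1),
    stromaIntensityMix = intensityMix(240L, 240L, 1),
    noiseSD = 0, seed = 2)
  img <- generateImage(spec)
  expect_setequal(unique(as.integer(pixels(img))), c(100L, 240L))
  expect_gt(sum(pixels(img) == 100L), 0)
})

test_that("same spec and seed give bit-identical images", {
  spec <- nestImageSpec(width = 96L, height = 80L, seed = 17)
  expect_identical(pixels(generateImage(spec)), pixels(generateImage(spec)))
  spec2 <- nestImageSpec(width = 96L, height = 80L, seed = 18)
  expect_false(identical(pixels(generateImage(spec)),
    pixels(generateImage(spec2))))
})

test_that("invalid mixture weights and sizes are rejected", {
  expect_error(intensityMix(c(0L, 100L), c(50L, 200L), c(0.5, 0.4)),
    "sum to 1")
  expect_error(intensityMix(0L, 300L, 1), "0 <= lo <= hi <= 255")
  expect_error(intensityMix(0L, 100L, -1), "non-negative")
  expect_error(nestImageSpec(width = 32L), ">= 64")
})

test_that("cohort invariants: record counts, prevalence modes, validation", {
  coh <- generateCohort(cohortSpec(nPatients = 25, imagesPerPatient = 3,
    seed = 4))
  expect_identical(nrow(coh$patients), 25L)
  expect_identical(nrow(coh$images), 75L)
  expect_identical(anyDuplicated(coh$images$image_id), 0L)

  exact <- generateCohort(cohortSpec(nPatients = 102, prevalence = 0.2,
    prevalenceMode = "exact", seed = 5))
  expect_identical(sum(exact$patients$outcome), 20L)

  set.seed(6)
  expect_error(cohortSpec(effectAuc = 1.2), "effectAuc")
  expect_error(cohortSpec(prevalence = 0), "prevalence")
})

test_that("binormal construction recovers the designed latent AUC", {
  for (a in c(0.6, 0.7, 0.8)) {
    coh <- generateCohort(cohortSpec(nPatients = 1000, effectAuc = a,
      seed = 100 + round(100 * a)))
    est <- rocAuc(coh$patients$latent, coh$patients$outcome)$auc
    expect_lt(abs(est - a), 0.04)
  }
  # null case: no information in the latent feature
  coh0 <- generateCohort(cohortSpec(nPatients = 500, effectAuc = 0.5,
    seed = 7))
  est0 <- rocAuc(coh0$patients$latent, coh0$patients$outcome)$auc
  expect_lt(abs(est0 - 0.5), 0.05)
})

test_that("cohorts are reproducible and latent level shifts nest counts", {
  c1 <- generateCohort(cohortSpec(nPatients = 30, seed = 8))
  c2 <- generateCohort(cohortSpec(nPatients = 30, seed = 8))
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$images, c2$images)
  expect_gt(cor(c1$patients$latent,
    tapply(c1$images$nest_count, c1$images$patient_id, mean)[
      c1$patients$patient_id]), 0.95)
})

test_that("writeCohort produces a readable manifest and images", {
  dir <- withr::local_tempdir()
  coh <- generateCohort(cohortSpec(nPatients = 3, imagesPerPatient = 2,
    seed = 9), nestImageSpec(width = 64L, height = 64L, nestCount = 5L))
  man <- writeCohort(coh, dir)
  m <- read.csv(man)
  expect_identical(nrow(m), 6L)
  expect_true(all(file.exists(m$image_path)))
  img <- readGreyImage(m$image_path[1])
  ref <- cohortImages(coh, 1)[[1]]
  expect_identical(pixels(img), pixels(ref))
  expect_true(file.exists(file.path(dir, "cohort_spec.json")))
})
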