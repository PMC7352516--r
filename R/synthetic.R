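#' Intensity mixture specification
#'
#' A discrete mixture of grey-level intervals used by the synthetic image
#' generator: each row gives an interval `lo..hi` and a weight; a pixel
#' drawn from the mixture picks a row by weight, then a uniform grey level
#' within the row's interval. An interval with `lo == hi` is a single grey
#' value. For `lo < hi` the draw is uniform over the open interval
#' (boundary levels excluded; for `lo = 0` level 0 is included), matching
#' the slicing kept-rule so that mixture weights translate directly into
#' range shares.
#'
#' @param lo,hi integer grey-level bounds per component.
#' @param weight non-negative weights, must sum to 1 (tolerance 1e-9).
#' @return data.frame with class `"intensity_mix"`.
#' @export
intensityMix <- function(lo, hi, weight) {
  m <- data.frame(lo = as.integer(lo), hi = as.integer(hi),
    weight = as.numeric(weight))
  if (any(m$lo < 0L | m$hi > 255L | m$lo > m$hi))
    stop("mixture grey levels must satisfy 0 <= lo <= hi <= 255")
  if (any(m$weight < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(m$weight) - 1) > 1e-9) stop("mixture weights must sum to 1")
  class(m) <- c("intensity_mix", "data.frame")
  m
}

#' @export
print.intensity_mix <- function(x, ...) {
  cat("intensity_mix:\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Default nest (specific staining) intensity mixture
#'
#' Grey levels of tumor-nest pixels across the five specific-staining
#' ranges (0-130, 130-160, 160-180, 180-200, 200-220), weighted in the
#' proportions 6:9:10:8:8 so that, at the default nest coverage of ~41% of
#' the image, the whole-image shares match the reported average
#' distribution of pan cytokeratin pixel intensities.
#' @return an [intensityMix()].
#' @export
defaultNestMix <- function() {
  intensityMix(
    lo = c(0L, 130L, 160L, 180L, 200L),
    hi = c(130L, 160L, 180L, 200L, 220L),
    weight = c(6, 9, 10, 8, 8) / 41)
}

#' Default stroma (non-specific staining) intensity mixture
#'
#' Grey levels of stroma pixels across the two non-specific ranges
#' (220-240, 240-255), weighted 29:30.
#' @return an [intensityMix()].
#' @export
defaultStromaMix <- function() {
  intensityMix(lo = c(220L, 240L), hi = c(240L, 255L),
    weight = c(29, 30) / 59)
}

#' Synthetic tumor-nest image specification
#'
#' Parameters of the synthetic pan cytokeratin image generator: a light
#' stroma background scattered with dark-staining epithelial tumor nests.
#' Nests are unions of randomly placed, randomly oriented ellipses
#' (overlaps merge), emulating patches of malignant epithelial cells of
#' variable sizes and shapes. The defaults are calibrated so that the
#' average pixel shares over the seven canonical ranges approximate
#' 6/9/10/8/8/29/30 percent.
#'
#' @param width,height image size in pixels (minimum 64).
#' @param nestCount number of ellipses placed.
#' @param nestRadiusMean,nestRadiusSD nest equivalent-radius distribution
#'   (pixels; normal, truncated at 2).
#' @param nestIntensityMix,stromaIntensityMix [intensityMix()] objects for
#'   nest and stroma pixels.
#' @param noiseSD additive Gaussian noise SD in grey levels (clipped to
#'   \[0,255\]; a message is emitted when more than 1% of pixels clip).
#' @param seed integer seed; the image is a deterministic function of the
#'   spec.
#' @return list with class `"nest_image_spec"`.
#' @export
nestImageSpec <- function(width = 256L, height = 256L, nestCount = 33L,
                          nestRadiusMean = 18, nestRadiusSD = 6,
                          nestIntensityMix = defaultNestMix(),
                          stromaIntensityMix = defaultStromaMix(),
                          noiseSD = 1, seed = 1L) {
  if (width < 64L || height < 64L) stop("width and height must be >= 64")
  if (nestCount < 0L) stop("nestCount must be non-negative")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  for (m in list(nestIntensityMix, stromaIntensityMix))
    if (!inherits(m, "intensity_mix"))
      stop("intensity mixes must be built with intensityMix()")
  structure(list(width = as.integer(width), height = as.integer(height),
    nestCount = as.integer(nestCount), nestRadiusMean = nestRadiusMean,
    nestRadiusSD = nestRadiusSD, nestIntensityMix = nestIntensityMix,
    stromaIntensityMix = stromaIntensityMix, noiseSD = noiseSD,
    seed = as.integer(seed)), class = "nest_image_spec")
}

sampleMix <- function(n, mix) {
  if (n == 0L) return(integer(0))
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  lo <- mix$lo[comp]; hi <- mix$hi[comp]
  # open-interval draw aligned with the slicing kept-rule
  lower <- ifelse(lo == 0L, 0L, pmin(lo + 1L, hi))
  upper <- ifelse(hi > lo, hi - 1L, hi)
  lower <- pmin(lower, upper)
  lower + floor(stats::runif(n) * (upper - lower + 1L))
}

#' Generate a synthetic tumor-nest image
#'
#' Places `nestCount` random ellipses (merging where they overlap) on a
#' stroma background, draws nest and stroma pixel intensities from their
#' mixtures, then adds clipped Gaussian noise. Deterministic given the
#' spec's seed.
#'
#' @param spec a [nestImageSpec()].
#' @return a [GreyImage-class] with attribute `"nest_fraction"`, the
#'   realised fraction of nest pixels.
#' @examples
#' img <- generateImage(nestImageSpec(seed = 7))
#' round(rangeShare(img), 3)
#' @export
generateImage <- function(spec) {
  stopifnot(inherits(spec, "nest_image_spec"))
  W <- spec$width; H <- spec$height
  withr::with_seed(spec$seed, {
    mask <- matrix(FALSE, W, H)
    if (spec$nestCount > 0L) {
      cx <- stats::runif(spec$nestCount, 1, W)
      cy <- stats::runif(spec$nestCount, 1, H)
      r <- pmax(stats::rnorm(spec$nestCount, spec$nestRadiusMean,
        spec$nestRadiusSD), 2)
      aspect <- stats::runif(spec$nestCount, 0.45, 1)
      theta <- stats::runif(spec$nestCount, 0, pi)
      for (i in seq_len(spec$nestCount)) {
        A <- r[i] / sqrt(aspect[i]); B <- r[i] * sqrt(aspect[i])
        x0 <- max(1L, floor(cx[i] - A)); x1 <- min(W, ceiling(cx[i] + A))
        y0 <- max(1L, floor(cy[i] - A)); y1 <- min(H, ceiling(cy[i] + A))
        if (x0 > x1 || y0 > y1) next
        xs <- x0:x1; ys <- y0:y1
        dx <- outer(xs - cx[i], rep(1, length(ys)))
        dy <- outer(rep(1, length(xs)), ys - cy[i])
        u <- (dx * cos(theta[i]) + dy * sin(theta[i])) / A
        v <- (-dx * sin(theta[i]) + dy * cos(theta[i])) / B
        mask[xs, ys] <- mask[xs, ys] | (u^2 + v^2 <= 1)
      }
    }
    px <- matrix(0L, W, H)
    nNest <- sum(mask)
    px[mask] <- sampleMix(nNest, spec$nestIntensityMix)
    px[!mask] <- sampleMix(W * H - nNest, spec$stromaIntensityMix)
    if (spec$noiseSD > 0) {
      noisy <- round(px + stats::rnorm(W * H, 0, spec$noiseSD))
      nClip <- sum(noisy < 0 | noisy > 255)
      if (nClip > 0.01 * W * H)
        message(sprintf("noise clipped %.1f%% of pixels", 100 * nClip / (W * H)))
      px <- matrix(as.integer(pmin(pmax(noisy, 0), 255)), W, H)
    }
  })
  img <- greyImage(px)
  attr(img, "nest_fraction") <- sum(mask) / (W * H)
  img
}

#' Synthetic cohort specification
#'
#' Shape of a simulated patient cohort: `nPatients` patients with
#' `imagesPerPatient` images each, a metastasis prevalence, and a latent
#' image property whose class-conditional distribution is shifted so that
#' it discriminates positive from negative patients with a chosen
#' population AUC (binormal construction: the latent mean differs between
#' classes by `delta = sqrt(2) * qnorm(effectAuc)`).
#'
#' @param nPatients number of patients (default 102).
#' @param imagesPerPatient images per patient (default 5, emulating five
#'   representative fields per section).
#' @param prevalence fraction of metastasis-positive patients, in (0, 1)
#'   (default 20/102).
#' @param effectFeature the latent property carrying the effect; currently
#'   `"nest_area_fraction"` (the per-patient nest coverage level).
#' @param effectAuc target discriminative AUC of the latent feature, in
#'   \[0.5, 1\].
#' @param effectScale logit-scale spread of per-patient nest coverage per
#'   latent SD; larger values make the image-measurable effect stronger
#'   relative to per-image sampling noise.
#' @param prevalenceMode `"binomial"` (default) draws each outcome
#'   independently; `"exact"` fixes the positive count to
#'   `round(prevalence * nPatients)`.
#' @param seed integer seed.
#' @return list with class `"cohort_spec"`.
#' @export
cohortSpec <- function(nPatients = 102L, imagesPerPatient = 5L,
                       prevalence = 20 / 102,
                       effectFeature = "nest_area_fraction",
                       effectAuc = 0.75, effectScale = 0.35,
                       prevalenceMode = c("binomial", "exact"),
                       seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (effectAuc < 0.5 || effectAuc > 1) stop("effectAuc must lie in [0.5, 1]")
  effectFeature <- match.arg(effectFeature, "nest_area_fraction")
  structure(list(nPatients = as.integer(nPatients),
    imagesPerPatient = as.integer(imagesPerPatient),
    prevalence = prevalence, effectFeature = effectFeature,
    effectAuc = effectAuc, effectScale = effectScale,
    prevalenceMode = match.arg(prevalenceMode), seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws outcomes and the latent effect feature by the binormal
#' construction of [cohortSpec()], simulates clinicopathological
#' covariates (age, tumor size in mm, ER status), and derives per-image
#' generator specs whose expected nest coverage follows the patient's
#' latent level: the latent value shifts the coverage on the logit scale
#' and the ellipse count is adjusted through the Boolean-coverage relation
#' `coverage = 1 - exp(-lambda)`. Images themselves are generated lazily by
#' [cohortImages()] or written out by [writeCohort()].
#'
#' @param spec a [cohortSpec()].
#' @param imageSpec baseline [nestImageSpec()] shared by all patients.
#' @return object of class `"synthetic_cohort"`: list with `patients`
#'   (data.frame: patient_id, outcome, latent, age, tumor_size, er_status),
#'   `images` (data.frame: patient_id, image_id, seed, nest_count), and the
#'   two specs.
#' @examples
#' coh <- generateCohort(cohortSpec(nPatients = 10, seed = 3))
#' table(coh$patients$outcome)
#' @export
generateCohort <- function(spec, imageSpec = nestImageSpec()) {
  stopifnot(inherits(spec, "cohort_spec"),
    inherits(imageSpec, "nest_image_spec"))
  n <- spec$nPatients
  withr::with_seed(spec$seed, {
    outcome <- if (spec$prevalenceMode == "binomial") {
      stats::rbinom(n, 1L, spec$prevalence)
    } else {
      k <- round(spec$prevalence * n)
      o <- integer(n); o[sample.int(n, k)] <- 1L; o
    }
    delta <- sqrt(2) * stats::qnorm(spec$effectAuc)
    latent <- stats::rnorm(n, mean = delta * outcome, sd = 1)
    age <- as.integer(pmin(pmax(round(stats::rnorm(n, 57, 10)), 30), 85))
    tumorSize <- round(stats::rlnorm(n, log(20), 0.35), 1)
    er <- stats::rbinom(n, 1L, 0.69)
    imgSeeds <- sample.int(.Machine$integer.max - 1L,
      n * spec$imagesPerPatient)
  })
  # map latent coverage level to ellipse counts via Boolean coverage
  f0 <- expectedNestCoverage(imageSpec)
  fPat <- stats::plogis(stats::qlogis(f0) + spec$effectScale * latent)
  lam0 <- -log(1 - f0)
  countPat <- pmax(1L, as.integer(round(
    imageSpec$nestCount * (-log(1 - fPat)) / lam0)))
  pid <- sprintf("P%03d", seq_len(n))
  patients <- data.frame(patient_id = pid, outcome = outcome,
    latent = latent, age = age, tumor_size = tumorSize, er_status = er)
  images <- data.frame(
    patient_id = rep(pid, each = spec$imagesPerPatient),
    image_id = paste0(rep(pid, each = spec$imagesPerPatient), "_img",
      rep(seq_len(spec$imagesPerPatient), n)),
    seed = imgSeeds,
    nest_count = rep(countPat, each = spec$imagesPerPatient))
  structure(list(patients = patients, images = images, spec = spec,
    imageSpec = imageSpec), class = "synthetic_cohort")
}

# Monte-Carlo-free estimate of expected union coverage of the ellipse
# process (Boolean model with edge-effect correction for centers falling
# inside the frame)
expectedNestCoverage <- function(imageSpec) {
  r2 <- imageSpec$nestRadiusMean^2 + imageSpec$nestRadiusSD^2
  meanArea <- pi * r2
  # centers are uniform over the frame, so roughly half of the area of
  # ellipses near the border falls outside; shrink by the boundary fraction
  rEff <- sqrt(r2)
  edge <- (1 - rEff / imageSpec$width) * (1 - rEff / imageSpec$height)
  lambda <- imageSpec$nestCount * meanArea * max(edge, 0.25) /
    (imageSpec$width * imageSpec$height)
  1 - exp(-lambda)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d patients (%d positive), %d images/patient, target AUC %.2f\n",
    nrow(x$patients), sum(x$patients$outcome),
    x$spec$imagesPerPatient, x$spec$effectAuc))
  invisible(x)
}

#' Realise the images of one patient (or of an image subset)
#'
#' @param cohort a [generateCohort()] result.
#' @param rows row indices into `cohort$images` (default: all).
#' @return named list of [GreyImage-class], names = image ids.
#' @export
cohortImages <- function(cohort, rows = seq_len(nrow(cohort$images))) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  out <- lapply(rows, function(i) {
    sp <- cohort$imageSpec
    sp$nestCount <- cohort$images$nest_count[i]
    sp$seed <- cohort$images$seed[i]
    generateImage(sp)
  })
  names(out) <- cohort$images$image_id[rows]
  out
}

#' Write a synthetic cohort to disk
#'
#' Generates every image, writes 8-bit greyscale files and a manifest CSV
#' (`patient_id, image_id, image_path, outcome, age, tumor_size,
#' er_status`; one row per image), and a JSON copy of both specs.
#'
#' @param cohort a [generateCohort()] result.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("png", "tiff")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort$images))
  for (i in seq_len(nrow(cohort$images))) {
    img <- cohortImages(cohort, i)[[1]]
    paths[i] <- file.path(dir,
      paste0(cohort$images$image_id[i], ".", format))
    writeGreyImage(img, paths[i])
  }
  man <- merge(cohort$images[, c("patient_id", "image_id")],
    cohort$patients[, c("patient_id", "outcome", "age", "tumor_size",
      "er_status")], by = "patient_id", sort = FALSE)
  man$image_path <- paths[match(man$image_id, cohort$images$image_id)]
  man <- man[order(man$image_id),
    c("patient_id", "image_id", "image_path", "outcome", "age",
      "tumor_size", "er_status")]
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  specs <- list(cohort_spec = unclass(cohort$spec),
    image_spec = lapply(unclass(cohort$imageSpec), function(x)
      if (inherits(x, "data.frame")) as.list(x) else x))
  jsonlite::write_json(specs, file.path(dir, "cohort_spec.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manPath)
}
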