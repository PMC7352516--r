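#' Names of the 33 canonical features
#'
#' Five GLCM texture features, 23 monofractal features and five
#' threshold-limited first-order statistics. The auxiliary derived `mean`
#' (= `int_den / area`) is emitted alongside but is not part of the
#' canonical count.
#'
#' @return character vector of length 33.
#' @export
featureNames <- function() {
  c("asm", "contrast", "correlation", "idm", "entropy",
    fractalFeatureNames(),
    "area", "int_den", "raw_int_den", "skewness", "kurtosis")
}

featureFamily <- function(feature) {
  glcmF <- c("asm", "contrast", "correlation", "idm", "entropy")
  foF <- c("area", "int_den", "raw_int_den", "skewness", "kurtosis", "mean")
  ifelse(feature %in% glcmF, "glcm",
    ifelse(feature %in% foF, "first_order", "fractal"))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the extraction and evaluation stages. The
#' configuration serialises to JSON and a short hash of it is embedded in
#' every output of [runPipeline()] so results are traceable to their
#' settings.
#'
#' @param ranges list of [IntensityRange-class] to analyse; default
#'   [analysisRanges()] (original + seven narrow + specific/non-specific).
#' @param boundary slicing boundary semantics, see [sliceImage()].
#' @param families feature families to compute.
#' @param glcmDistance,glcmAngle,glcmSymmetric GLCM parameters, see
#'   [glcm()].
#' @param counting,nGrids,boxSizes,gridSeed fractal-scan parameters, see
#'   [fractalFeatures()]; `boxSizes = NULL` uses [defaultBoxSizes()]
#'   (sizes beyond the image are dropped at scan time).
#' @param bootstrap bootstrap resamples for internal validation of
#'   significant features (0 disables).
#' @param bootstrapSeed seed for the bootstrap.
#' @param entry,remain stepwise criteria, see [stepwiseLogistic()].
#' @param covariates clinicopathological columns offered to the stepwise
#'   model alongside significant image features.
#' @return list with class `"pipeline_config"`.
#' @export
pipelineConfig <- function(ranges = analysisRanges(),
                           boundary = c("macro", "inclusive-lower"),
                           families = c("glcm", "fractal", "first_order"),
                           glcmDistance = 1L, glcmAngle = 0,
                           glcmSymmetric = TRUE,
                           counting = c("binary", "differential", "span"),
                           nGrids = 12L, boxSizes = NULL, gridSeed = 1L,
                           bootstrap = 1000L, bootstrapSeed = 7L,
                           entry = 0.05, remain = 0.05,
                           covariates = c("age", "tumor_size", "er_status")) {
  structure(list(ranges = ranges, boundary = match.arg(boundary),
    families = match.arg(families, several.ok = TRUE),
    glcmDistance = glcmDistance, glcmAngle = glcmAngle,
    glcmSymmetric = glcmSymmetric, counting = match.arg(counting),
    nGrids = nGrids, boxSizes = boxSizes, gridSeed = gridSeed,
    bootstrap = bootstrap, bootstrapSeed = bootstrapSeed,
    entry = entry, remain = remain, covariates = covariates),
    class = "pipeline_config")
}

configJSON <- function(config) {
  x <- unclass(config)
  x$ranges <- vapply(x$ranges, function(r)
    sprintf("%d-%d", r@lo, r@hi), character(1))
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

# small polynomial rolling hash for config fingerprinting
configHash <- function(config) {
  bytes <- utf8ToInt(as.character(configJSON(config)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  # split into two 16-bit halves so sprintf sees integers
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Extract the 33 features for every image and range
#'
#' For each image and each intensity range the image is sliced
#' (out-of-range pixels to white), GLCM and fractal features are computed
#' on the white-filled slice (fill pixels participate), and first-order
#' statistics strictly on the kept pixels. One row per image x range.
#' Unreadable images are skipped with a warning and the run continues.
#'
#' @param images named list of [GreyImage-class] objects, or a character
#'   vector of image paths (names become image ids; unnamed paths use the
#'   file name).
#' @param config a [pipelineConfig()].
#' @return data.frame: `image_id`, `range_label`, the 33 columns of
#'   [featureNames()], and the auxiliary `mean`. Undefined feature values
#'   are `NA`, never silent zeros.
#' @export
extractFeatures <- function(images, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(images)) {
    nms <- if (is.null(names(images)))
      tools::file_path_sans_ext(basename(images)) else names(images)
    paths <- images
    images <- stats::setNames(vector("list", length(paths)), nms)
    for (i in seq_along(paths)) {
      images[[i]] <- tryCatch(readGreyImage(paths[i]), error = function(e) {
        warning("skipping unreadable image '", paths[i], "': ",
          conditionMessage(e))
        NULL
      })
    }
    images <- Filter(Negate(is.null), images)
  }
  if (is.null(names(images)))
    names(images) <- sprintf("img%03d", seq_along(images))
  boxSizes <- config$boxSizes
  rows <- list()
  for (id in names(images)) {
    img <- images[[id]]
    bs <- if (is.null(boxSizes)) {
      b <- defaultBoxSizes()
      b[b <= min(dim(img))]
    } else boxSizes
    for (r in config$ranges) {
      sl <- sliceImage(img, r, config$boundary)
      vals <- c()
      if ("glcm" %in% config$families) {
        vals <- c(vals, glcmFeatures(glcm(sl, config$glcmDistance,
          config$glcmAngle, config$glcmSymmetric)))
      }
      if ("fractal" %in% config$families) {
        vals <- c(vals, suppressMessages(fractalFeatures(sl,
          nGrids = config$nGrids, boxSizes = bs, seed = config$gridSeed,
          counting = config$counting)))
      }
      if ("first_order" %in% config$families) {
        fo <- firstOrder(sl)
        vals <- c(vals, fo[c("area", "int_den", "raw_int_den",
          "skewness", "kurtosis", "mean")])
      }
      rows[[length(rows) + 1L]] <- data.frame(image_id = id,
        range_label = r@label, as.list(vals), check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average features per patient into a cohort table
#'
#' Joins the long feature table with a manifest mapping each image to its
#' patient, outcome and covariates, and averages every feature per patient
#' and range over that patient's images. Undefined (`NA`) values are
#' excluded from each mean (their count is reported in a message);
#' patients with no valid images are dropped with a warning.
#'
#' @param features long data.frame from [extractFeatures()].
#' @param manifest data.frame with columns `patient_id`, `image_id`,
#'   `outcome` and optional covariate columns (e.g. `age`, `tumor_size`,
#'   `er_status`).
#' @return wide data.frame, one row per patient: `patient_id`, `outcome`,
#'   covariates, then one column per `range.feature` combination (names
#'   like `"160-180.d_b"`).
#' @export
aggregatePatients <- function(features, manifest) {
  stopifnot(all(c("patient_id", "image_id", "outcome") %in% names(manifest)))
  unknown <- setdiff(features$image_id, manifest$image_id)
  if (length(unknown))
    stop("images missing from manifest: ", paste(unknown, collapse = ", "))
  feats <- merge(features, manifest[, c("patient_id", "image_id")],
    by = "image_id", sort = FALSE)
  valCols <- setdiff(names(features), c("image_id", "range_label"))
  covCols <- setdiff(names(manifest),
    c("patient_id", "image_id", "image_path"))
  pats <- unique(manifest[, c("patient_id", covCols), drop = FALSE])
  if (anyDuplicated(pats$patient_id))
    stop("inconsistent outcome/covariates within a patient")
  noImg <- setdiff(pats$patient_id, feats$patient_id)
  if (length(noImg)) {
    warning("patients with no valid images dropped: ",
      paste(noImg, collapse = ", "))
    pats <- pats[!pats$patient_id %in% noImg, ]
  }
  nDropped <- 0L
  wide <- pats[order(pats$patient_id), , drop = FALSE]
  rownames(wide) <- NULL
  for (rl in unique(feats$range_label)) {
    sub <- feats[feats$range_label == rl, ]
    for (vc in valCols) {
      v <- tapply(sub[[vc]], sub$patient_id, function(x) {
        nDropped <<- nDropped + sum(is.na(x) & any(!is.na(x)))
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      })
      wide[[paste(rl, vc, sep = ".")]] <- as.numeric(v[wide$patient_id])
    }
  }
  if (nDropped > 0)
    message(nDropped, " undefined feature value(s) excluded from patient means")
  wide
}
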