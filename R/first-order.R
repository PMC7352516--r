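#' Threshold-limited first-order statistics
#'
#' First-order statistics computed strictly within a grey-level range: only
#' the kept pixels enter (white fill and out-of-range pixels are excluded,
#' unlike the texture and fractal features which see the whole white-filled
#' image). The canonical five are area, integrated density, raw integrated
#' density, skewness and kurtosis; the mean is emitted as a derived
#' auxiliary value (`int_den / area`).
#'
#' Moments use the population (biased) estimators, the behaviour of common
#' image-measurement tools; kurtosis is the excess convention (fourth
#' standardised moment minus 3). Set `sample = TRUE` for the bias-corrected
#' sample estimators. Skewness and kurtosis are `NA` (undefined) when the
#' kept-pixel standard deviation is zero or fewer than 4 pixels are kept.
#' An empty kept set yields zero area/densities and `NA` for the moment
#' features, never an error.
#'
#' @param img a [GreyImage-class] or [SlicedImage-class]. Passing a slice
#'   reuses its kept mask; its `range` argument must then be missing or
#'   equal to the slice's range.
#' @param range an [IntensityRange-class] (required for a `GreyImage`).
#' @param sample use bias-corrected sample moments instead of population
#'   moments.
#' @param boundary boundary semantics, see [sliceImage()].
#' @return named numeric vector: `area` (pixels), `mean` (grey levels),
#'   `int_den` (mean x area), `raw_int_den` (sum of kept grey values),
#'   `skewness`, `kurtosis` (excess), and `area_um2` (`NA` when the image
#'   carries no pixel-size calibration).
#' @examples
#' img <- greyImage(matrix(c(100L, 150L, 170L, 190L, 210L, 230L, 250L, 255L, 160L), 3, 3))
#' firstOrder(img, intensityRange(160, 180))["area"]  # 1 (only the 170)
#' @export
firstOrder <- function(img, range, sample = FALSE,
                       boundary = c("macro", "inclusive-lower")) {
  if (is(img, "SlicedImage")) {
    if (!missing(range) && !identical(range@label, img@range@label))
      stop("range differs from the slice's own range")
    kept <- img@keptMask
    v <- as.numeric(img@image@pixels[kept])
    psz <- img@image@pixelSize
  } else {
    stopifnot(is(img, "GreyImage"), is(range, "IntensityRange"))
    kept <- keptRule(img@pixels, range, match.arg(boundary))
    v <- as.numeric(img@pixels[kept])
    psz <- img@pixelSize
  }
  area <- length(v)
  raw <- sum(v)
  m <- if (area > 0) raw / area else NA_real_
  intden <- if (area > 0) m * area else 0
  skew <- kurt <- NA_real_
  if (area >= 4) {
    m2 <- sum((v - m)^2) / area
    if (m2 > 0) {
      m3 <- sum((v - m)^3) / area
      m4 <- sum((v - m)^4) / area
      if (sample) {
        n <- area
        skew <- sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
        kurt <- (n - 1) / ((n - 2) * (n - 3)) *
          ((n + 1) * (m4 / m2^2 - 3) + 6)
      } else {
        skew <- m3 / m2^1.5
        kurt <- m4 / m2^2 - 3
      }
    }
  }
  c(area = area,
    mean = m,
    int_den = intden,
    raw_int_den = raw,
    skewness = skew,
    kurtosis = kurt,
    area_um2 = if (is.na(psz)) NA_real_ else area * psz^2)
}
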