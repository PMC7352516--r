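#' @import methods
NULL

#' GreyImage: an 8-bit greyscale intensity raster
#'
#' The central image container. Pixel values are integers in \[0, 255\] with
#' the brightfield immunohistochemistry convention: 0 is black (maximal
#' stain), 255 is white (no stain). Lower values therefore always mean
#' stronger staining.
#'
#' @slot pixels integer matrix of grey levels in \[0, 255\]; rows index the
#'   image x (horizontal) axis, columns the y (vertical) axis.
#' @slot pixelSize physical pixel edge length in micrometres, or `NA_real_`
#'   when the image is uncalibrated.
#'
#' @seealso [greyImage()], [readGreyImage()], [sliceImage()]
#' @exportClass GreyImage
setClass("GreyImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixels = matrix(255L, 1, 1), pixelSize = NA_real_)
)

setValidity("GreyImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric/integer matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (anyNA(p)) return("pixels must not contain NA")
  if (any(p != as.integer(p))) return("pixels must be whole numbers")
  if (min(p) < 0 || max(p) > 255) return("pixels must lie in [0, 255]")
  if (length(object@pixelSize) != 1L) return("pixelSize must be a single value")
  if (!is.na(object@pixelSize) && object@pixelSize <= 0)
    return("pixelSize must be positive")
  TRUE
})

#' IntensityRange: one grey-level slicing interval
#'
#' A labelled interval \[lo, hi\] of the 8-bit grey scale. The kept-pixel
#' rule applied by [sliceImage()] follows the slicing macro semantics: both
#' shared boundary levels are whitened (`lo < v < hi`), except that for
#' `lo = 0` level 0 itself is kept (`0 <= v < hi`), since there is no lower
#' neighbouring range whose command would whiten it.
#'
#' @slot lo,hi integer grey levels, `0 <= lo < hi <= 255`.
#' @slot label display label, e.g. `"160-180"`.
#'
#' @seealso [intensityRange()], [defaultRanges()]
#' @exportClass IntensityRange
setClass("IntensityRange",
  representation(lo = "integer", hi = "integer", label = "character")
)

setValidity("IntensityRange", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L)
    return("lo and hi must be single integers")
  if (is.na(object@lo) || is.na(object@hi)) return("lo/hi must not be NA")
  if (object@lo < 0L || object@hi > 255L) return("grey levels must lie in [0, 255]")
  if (object@lo >= object@hi) return("lo must be strictly below hi")
  if (length(object@label) != 1L || is.na(object@label))
    return("label must be a single string")
  TRUE
})

#' SlicedImage: a GreyImage restricted to one intensity range
#'
#' Produced by [sliceImage()]. Out-of-range pixels are replaced by white
#' (255); `keptMask` records which pixels belong to the range. Pixels that
#' were natively 255 are indistinguishable from fill in `image`, so the mask
#' is the authoritative record of range membership and is carried through
#' all downstream feature computations.
#'
#' @slot image the white-filled [GreyImage-class].
#' @slot keptMask logical matrix, `TRUE` exactly where the original pixel
#'   satisfied the kept rule of the range.
#' @slot range the [IntensityRange-class] that was applied.
#'
#' @exportClass SlicedImage
setClass("SlicedImage",
  representation(image = "GreyImage", keptMask = "matrix", range = "IntensityRange")
)

setValidity("SlicedImage", function(object) {
  if (!is.logical(object@keptMask)) return("keptMask must be logical")
  if (!identical(dim(object@keptMask), dim(object@image@pixels)))
    return("keptMask and image dimensions differ")
  if (any(object@image@pixels[!object@keptMask] != 255L))
    return("all non-kept pixels must be white (255)")
  TRUE
})
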