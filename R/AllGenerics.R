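#' Accessors for image classes
#'
#' `pixels()` returns the raw integer matrix of grey levels, `pixelSize()`
#' the micrometre calibration (or `NA`), `keptMask()` the logical
#' range-membership mask of a [SlicedImage-class], and `sliceRange()` the
#' [IntensityRange-class] a slice was made with. `lo()`, `hi()` and
#' `rangeLabel()` access the interval bounds and label.
#'
#' @param x a [GreyImage-class], [SlicedImage-class] or
#'   [IntensityRange-class] object, as appropriate.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("keptMask", function(x) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setGeneric("sliceRange", function(x) standardGeneric("sliceRange"))

#' @rdname accessors
#' @export
setGeneric("lo", function(x) standardGeneric("lo"))

#' @rdname accessors
#' @export
setGeneric("hi", function(x) standardGeneric("hi"))

#' @rdname accessors
#' @export
setGeneric("rangeLabel", function(x) standardGeneric("rangeLabel"))

#' @rdname accessors
#' @export
setMethod("pixels", "GreyImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "SlicedImage", function(x) x@image@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "GreyImage", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("pixelSize", "SlicedImage", function(x) x@image@pixelSize)

#' @rdname accessors
#' @export
setMethod("keptMask", "SlicedImage", function(x) x@keptMask)

#' @rdname accessors
#' @export
setMethod("sliceRange", "SlicedImage", function(x) x@range)

#' @rdname accessors
#' @export
setMethod("lo", "IntensityRange", function(x) x@lo)

#' @rdname accessors
#' @export
setMethod("hi", "IntensityRange", function(x) x@hi)

#' @rdname accessors
#' @export
setMethod("rangeLabel", "IntensityRange", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("rangeLabel", "SlicedImage", function(x) x@range@label)

setMethod("show", "GreyImage", function(object) {
  d <- dim(object@pixels)
  cal <- if (is.na(object@pixelSize)) "uncalibrated" else
    sprintf("%.3g um/px", object@pixelSize)
  cat(sprintf("GreyImage %d x %d (%s), grey levels %d..%d\n",
    d[1], d[2], cal, min(object@pixels), max(object@pixels)))
})

setMethod("show", "IntensityRange", function(object) {
  cat(sprintf("IntensityRange %s [lo=%d, hi=%d]\n",
    object@label, object@lo, object@hi))
})

setMethod("show", "SlicedImage", function(object) {
  d <- dim(object@keptMask)
  cat(sprintf("SlicedImage %s: %d x %d, %d kept pixels (%.1f%%)\n",
    object@range@label, d[1], d[2], sum(object@keptMask),
    100 * mean(object@keptMask)))
})

#' @rdname dim
#' @export
setMethod("dim", "GreyImage", function(x) dim(x@pixels))

#' Image dimensions
#'
#' Width (rows of the pixel matrix) and height for image objects.
#' @param x image object
#' @name dim
#' @export
setMethod("dim", "SlicedImage", function(x) dim(x@image@pixels))
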