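#' Construct an IntensityRange
#'
#' @param lo,hi grey levels with `0 <= lo < hi <= 255`.
#' @param label display label; defaults to `"lo-hi"`.
#' @return an [IntensityRange-class].
#' @examples
#' intensityRange(160, 180)
#' @export
intensityRange <- function(lo, hi, label = sprintf("%d-%d", lo, hi)) {
  new("IntensityRange", lo = as.integer(lo), hi = as.integer(hi), label = label)
}

#' The seven default narrow grey-level ranges
#'
#' The canonical slicing scheme for pan cytokeratin immunostaining:
#' 0-130, 130-160, 160-180, 180-200, 200-220, 220-240 and 240-255. The two
#' darkest ranges are wider because intense staining is rare; 220 is the
#' cutoff between specific (epithelial) and non-specific (stromal) staining.
#'
#' @return list of seven [IntensityRange-class] objects.
#' @seealso [analysisRanges()] for the full evaluation set.
#' @export
defaultRanges <- function() {
  b <- c(0L, 130L, 160L, 180L, 200L, 220L, 240L, 255L)
  lapply(seq_len(7), function(i) intensityRange(b[i], b[i + 1]))
}

#' The full range set used for prognostic evaluation
#'
#' The original image (0-255), the seven narrow ranges, and the specific
#' (0-220) and non-specific (220-255) staining compartments: ten ranges.
#'
#' @return list of ten [IntensityRange-class] objects.
#' @export
analysisRanges <- function() {
  c(list(intensityRange(0, 255)), defaultRanges(),
    list(intensityRange(0, 220), intensityRange(220, 255)))
}

keptRule <- function(v, range, boundary = c("macro", "inclusive-lower")) {
  boundary <- match.arg(boundary)
  if (boundary == "macro") {
    # macro semantics: both boundary levels whitened; for lo = 0 only the
    # upper command applies, so level 0 is kept. Level 255 is never kept.
    if (range@lo == 0L) v < range@hi else v > range@lo & v < range@hi
  } else {
    # prose semantics: lower boundary inclusive, upper exclusive
    v >= range@lo & v < range@hi
  }
}

#' Slice a GreyImage to one narrow intensity range
#'
#' Applies the grey-level slicing rule: pixels inside the range are kept,
#' all others are converted to white (255). The kept rule follows the
#' two-command macro semantics literally: a pixel `v` is kept iff
#' `lo < v < hi` (both shared boundary levels are whitened). For `lo = 0`
#' there is no lower command, so `0 <= v < hi` is kept. Level 255 never
#' counts as kept.
#'
#' @param img a [GreyImage-class].
#' @param range an [IntensityRange-class].
#' @param boundary `"macro"` (default; both boundary levels whitened) or
#'   `"inclusive-lower"` (lower boundary kept), for users preferring the
#'   inclusive range labelling over the literal macro behaviour.
#' @return a [SlicedImage-class].
#' @examples
#' img <- greyImage(matrix(c(100L, 160L, 170L, 180L), 2, 2))
#' s <- sliceImage(img, intensityRange(160, 180))
#' sum(keptMask(s))  # only the 170 pixel survives
#' @export
sliceImage <- function(img, range, boundary = c("macro", "inclusive-lower")) {
  stopifnot(is(img, "GreyImage"), is(range, "IntensityRange"))
  kept <- keptRule(img@pixels, range, boundary)
  px <- img@pixels
  px[!kept] <- 255L
  new("SlicedImage",
    image = greyImage(px, pixelSize = img@pixelSize),
    keptMask = kept, range = range)
}

#' Slice a GreyImage by every range in a set
#'
#' With the default seven ranges, every grey level except the shared
#' boundary levels (130, 160, 180, 200, 220, 240) and white 255 appears in
#' exactly one range's kept set. Ranges that overlap beyond a shared
#' boundary trigger a warning, not an error.
#'
#' @param img a [GreyImage-class].
#' @param ranges list of [IntensityRange-class]; default [defaultRanges()].
#' @param boundary boundary semantics, see [sliceImage()].
#' @return named list of [SlicedImage-class], one per range.
#' @export
sliceAll <- function(img, ranges = defaultRanges(),
                     boundary = c("macro", "inclusive-lower")) {
  stopifnot(is(img, "GreyImage"))
  n <- length(ranges)
  if (n > 1) {
    b <- t(vapply(ranges, function(r) c(r@lo, r@hi), integer(2)))
    ord <- order(b[, 1], b[, 2])
    if (any(b[ord[-n], 2] > b[ord[-1], 1]))
      warning("ranges overlap beyond shared boundaries; kept sets will not partition")
  }
  out <- lapply(ranges, function(r) sliceImage(img, r, boundary))
  names(out) <- vapply(ranges, function(r) r@label, character(1))
  out
}

#' Fraction of image pixels kept in each range
#'
#' @param img a [GreyImage-class].
#' @param ranges list of [IntensityRange-class]; default [defaultRanges()].
#' @param boundary boundary semantics, see [sliceImage()].
#' @return named numeric vector of per-range kept fractions (relative to the
#'   total pixel count; with disjoint ranges the sum is at most 1, the
#'   remainder being boundary levels and white pixels).
#' @export
rangeShare <- function(img, ranges = defaultRanges(),
                       boundary = c("macro", "inclusive-lower")) {
  stopifnot(is(img, "GreyImage"))
  boundary <- match.arg(boundary)
  npx <- length(img@pixels)
  sh <- vapply(ranges, function(r) sum(keptRule(img@pixels, r, boundary)) / npx,
    numeric(1))
  names(sh) <- vapply(ranges, function(r) r@label, character(1))
  sh
}

#' Binary mask of a sliced image
#'
#' @param sliced a [SlicedImage-class].
#' @return integer matrix with kept pixels 255 (white) and others 0 (black),
#'   mirroring the usual binary-mask rendering of the staining pattern.
#' @export
binaryMask <- function(sliced) {
  stopifnot(is(sliced, "SlicedImage"))
  m <- matrix(0L, nrow(sliced@keptMask), ncol(sliced@keptMask))
  m[sliced@keptMask] <- 255L
  m
}

#' Red overlay of a slice on the original image
#'
#' Replicates the original grey image into RGB and paints the kept pixels of
#' the slice pure red, visualising where one staining intensity range lives
#' within the tissue.
#'
#' @param img the original [GreyImage-class].
#' @param sliced a [SlicedImage-class] computed from `img`.
#' @return width x height x 3 integer array in \[0, 255\].
#' @export
overlayImage <- function(img, sliced) {
  stopifnot(is(img, "GreyImage"), is(sliced, "SlicedImage"))
  if (!identical(dim(img@pixels), dim(sliced@keptMask)))
    stop("image and slice dimensions differ")
  g <- img@pixels
  out <- array(as.integer(g), dim = c(dim(g), 3L))
  r <- out[, , 1]; gg <- out[, , 2]; b <- out[, , 3]
  r[sliced@keptMask] <- 255L
  gg[sliced@keptMask] <- 0L
  b[sliced@keptMask] <- 0L
  out[, , 1] <- r; out[, , 2] <- gg; out[, , 3] <- b
  out
}
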