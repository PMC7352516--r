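#' Construct a GreyImage from a matrix
#'
#' @param pixels numeric or integer matrix with values in \[0, 255\].
#' @param pixelSize physical pixel size in micrometres per pixel, `NA` if
#'   unknown.
#' @return a [GreyImage-class].
#' @examples
#' img <- greyImage(matrix(200L, 10, 10))
#' intensityHistogram(img)[201]  # level 200 -> 100 pixels
#' @export
greyImage <- function(pixels, pixelSize = NA_real_) {
  if (is.double(pixels) && any(pixels != round(pixels), na.rm = TRUE))
    stop("pixels must be whole numbers in [0, 255]")
  storage.mode(pixels) <- "integer"
  new("GreyImage", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Read an 8-bit greyscale or RGB raster image
#'
#' Loads a PNG or TIFF losslessly. Greyscale input becomes a
#' [GreyImage-class]; RGB input is returned as an integer array of
#' dimension `c(width, height, 3)` with class attribute `"rgb_raster"`,
#' flagged for stain decomposition with [decomposeStains()]. Images with
#' more than 8 bits per sample are rejected: the slicing analysis is
#' defined on the 0..255 grey scale.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixelSize optional micrometres-per-pixel calibration stored on the
#'   result.
#' @return a [GreyImage-class] or an `"rgb_raster"` array.
#' @export
readGreyImage <- function(path, pixelSize = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
    if (!is.null(depth) && depth > 8)
      stop("unsupported bit depth (", depth, "-bit): only 8-bit images are supported")
    arr <- round(raw * 255)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
    if (!is.null(depth) && depth > 8)
      stop("unsupported bit depth (", depth, "-bit): only 8-bit images are supported")
    arr <- round(raw * 255)
  } else {
    stop("unsupported image format '", ext, "': use 8-bit PNG or TIFF")
  }
  # drop a fully opaque alpha channel if present
  if (length(dim(arr)) == 3 && dim(arr)[3] %in% c(2L, 4L)) {
    alpha <- arr[, , dim(arr)[3]]
    if (any(alpha != 255)) warning("alpha channel ignored")
    arr <- arr[, , -dim(arr)[3], drop = FALSE]
    if (dim(arr)[3] == 1L) arr <- arr[, , 1]
  }
  # readers return row = y; transpose to the package's x-major convention
  # (and strip any reader metadata attributes)
  if (length(dim(arr)) == 2) {
    m <- t(arr)
    greyImage(matrix(as.integer(m), nrow(m), ncol(m)),
      pixelSize = pixelSize)
  } else {
    out <- aperm(arr, c(2, 1, 3))
    out <- array(as.integer(out), dim = dim(out))
    class(out) <- "rgb_raster"
    attr(out, "pixelSize") <- as.numeric(pixelSize)
    out
  }
}

#' Write a GreyImage (or raster matrix) to PNG or TIFF
#'
#' @param img a [GreyImage-class], a \[0,255\] matrix, or a
#'   width x height x 3 RGB array in \[0,255\].
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writeGreyImage <- function(img, path) {
  arr <- if (is(img, "GreyImage")) img@pixels else unclass(img)
  arr <- arr / 255
  # back to the readers' row = y convention
  arr <- if (length(dim(arr)) == 2) t(arr) else aperm(arr, c(2, 1, 3))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L, compression = "none")
  } else {
    stop("unsupported output format: ", ext)
  }
  invisible(path)
}

#' Default stain vectors for optical-density colour deconvolution
#'
#' Unit RGB absorbance vectors for a hematoxylin-like blue stain and a
#' DAB-like brown stain (Ruifrok-Johnston values). Used by
#' [decomposeStains()]; both are configurable there.
#'
#' @return a 2 x 3 matrix with rows `blue` and `brown`.
#' @export
defaultStainVectors <- function() {
  m <- rbind(
    blue  = c(0.650, 0.704, 0.286),
    brown = c(0.268, 0.570, 0.776)
  )
  m / sqrt(rowSums(m^2))
}

#' Separate blue and brown stains from an RGB brightfield image
#'
#' Standard optical-density colour deconvolution. Per pixel the RGB optical
#' density `OD = -log10(I/255)` is decomposed onto two configurable stain
#' absorbance vectors plus an orthogonal residual, and each stain density
#' `c` is rendered back to an 8-bit grey channel as `255 * 10^(-c)`, so 255
#' means no stain and darker means denser stain. Downstream slicing analysis
#' consumes the blue (pan cytokeratin) channel only.
#'
#' @param rgb an `"rgb_raster"` array as returned by [readGreyImage()], or
#'   any width x height x 3 array of \[0,255\] values.
#' @param stains 2 x 3 matrix of stain absorbance vectors (rows), defaults
#'   to [defaultStainVectors()].
#' @return list with [GreyImage-class] components `blue` and `brown`.
#' @export
decomposeStains <- function(rgb, stains = defaultStainVectors()) {
  arr <- unclass(rgb)
  if (length(dim(arr)) != 3 || dim(arr)[3] != 3)
    stop("rgb must be a width x height x 3 array")
  stains <- as.matrix(stains)
  if (!identical(dim(stains), c(2L, 3L))) stop("stains must be a 2 x 3 matrix")
  stains <- stains / sqrt(rowSums(stains^2))
  resid <- c(
    stains[1, 2] * stains[2, 3] - stains[1, 3] * stains[2, 2],
    stains[1, 3] * stains[2, 1] - stains[1, 1] * stains[2, 3],
    stains[1, 1] * stains[2, 2] - stains[1, 2] * stains[2, 1]
  )
  if (sqrt(sum(resid^2)) < 1e-6)
    stop("degenerate (collinear) stain vectors")
  M <- rbind(stains, resid / sqrt(sum(resid^2)))
  dims <- dim(arr)[1:2]
  I <- matrix(pmax(as.numeric(arr), 1), ncol = 3) # avoid log(0)
  od <- -log10(I / 255)
  dens <- od %*% solve(M) # per-pixel densities in rows of M
  toGrey <- function(c0) {
    g <- round(255 * 10^(-pmax(c0, 0)))
    greyImage(matrix(as.integer(pmin(pmax(g, 0), 255)), dims[1], dims[2]),
      pixelSize = if (is.null(attr(rgb, "pixelSize"))) NA_real_ else
        attr(rgb, "pixelSize"))
  }
  list(blue = toGrey(dens[, 1]), brown = toGrey(dens[, 2]))
}

#' Intensity histogram of a GreyImage
#'
#' @param img a [GreyImage-class].
#' @return integer vector of length 256, named `"0"`..`"255"`; counts sum to
#'   the pixel count.
#' @export
intensityHistogram <- function(img) {
  stopifnot(is(img, "GreyImage"))
  h <- tabulate(as.integer(img@pixels) + 1L, nbins = 256L)
  names(h) <- 0:255
  h
}
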