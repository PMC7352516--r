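#' Grey-level co-occurrence matrix
#'
#' Joint probability of grey-level pairs at a fixed pixel offset, over the
#' full 256-level scale (no quantisation). Defaults follow the common
#' texture-plugin convention: distance 1, angle 0 degrees (horizontal
#' neighbour), symmetric accumulation. For sliced images the white fill
#' pixels participate fully: pass `pixels(sliced)` like any other image.
#'
#' @param img a [GreyImage-class], [SlicedImage-class] or a \[0,255\] matrix.
#' @param distance offset length in pixels (default 1).
#' @param angle offset direction in degrees, one of 0, 45, 90, 135. 0 is
#'   along increasing x, 90 along increasing y.
#' @param symmetric if `TRUE` (default) each pair is counted in both
#'   orders, making the matrix symmetric.
#' @return a 256 x 256 matrix of probabilities summing to 1, with
#'   `dimnames` `0..255`.
#' @examples
#' p <- glcm(greyImage(matrix(c(5L, 9L), 1, 2)))
#' p["5", "9"]  # 0.5
#' @export
glcm <- function(img, distance = 1L, angle = 0, symmetric = TRUE) {
  v <- if (is(img, "GreyImage")) img@pixels else
    if (is(img, "SlicedImage")) img@image@pixels else img
  stopifnot(is.matrix(v))
  storage.mode(v) <- "integer"
  if (!(angle %in% c(0, 45, 90, 135)))
    stop("angle must be one of 0, 45, 90, 135")
  d <- as.integer(distance)
  if (d < 1L) stop("distance must be >= 1")
  off <- switch(as.character(angle),
    "0"   = c(d, 0L),
    "45"  = c(d, -d),
    "90"  = c(0L, d),
    "135" = c(-d, -d))
  W <- nrow(v); H <- ncol(v)
  xi <- seq_len(W - abs(off[1])); yi <- seq_len(H - abs(off[2]))
  if (length(xi) < 1L || length(yi) < 1L)
    stop("image too small for the requested offset")
  # reference pixel indices such that (x1,y1) + off = (x2,y2), all in range
  x1 <- xi + max(-off[1], 0L); x2 <- xi + max(off[1], 0L)
  y1 <- yi + max(-off[2], 0L); y2 <- yi + max(off[2], 0L)
  a <- v[x1, y1, drop = FALSE]; b <- v[x2, y2, drop = FALSE]
  idx <- as.integer(a) * 256L + as.integer(b) + 1L
  counts <- tabulate(idx, nbins = 256L * 256L)
  if (symmetric) {
    idx2 <- as.integer(b) * 256L + as.integer(a) + 1L
    counts <- counts + tabulate(idx2, nbins = 256L * 256L)
  }
  p <- matrix(counts / sum(counts), 256L, 256L, byrow = TRUE,
    dimnames = list(0:255, 0:255))
  p
}

#' Haralick texture features of a co-occurrence matrix
#'
#' The five classical features: angular second moment
#' `ASM = sum p^2`, `contrast = sum (i-j)^2 p`, `correlation =
#' sum (i - mu_x)(j - mu_y) p / (sigma_x sigma_y)`,  inverse difference
#' moment `IDM = sum p / (1 + (i-j)^2)` and `entropy = -sum p log p`
#' (natural logarithm). Correlation is returned as `NA` (undefined) when
#' either marginal standard deviation is zero, e.g. on a constant image.
#'
#' @param p a normalised co-occurrence matrix from [glcm()].
#' @return named numeric vector with elements `asm`, `contrast`,
#'   `correlation`, `idm`, `entropy`.
#' @examples
#' glcmFeatures(glcm(greyImage(matrix(100L, 4, 4))))
#' @export
glcmFeatures <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (abs(sum(p) - 1) > 1e-8) stop("p must be a normalised probability matrix")
  n <- nrow(p)
  lev <- seq_len(n) - 1
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  dif <- outer(lev, lev, "-")
  asm <- sum(p^2)
  contrast <- sum(dif^2 * p)
  idm <- sum(p / (1 + dif^2))
  pos <- p > 0
  entropy <- -sum(p[pos] * log(p[pos]))
  correlation <- if (sx * sy == 0) NA_real_ else
    sum(outer(lev - mux, lev - muy) * p) / (sx * sy)
  c(asm = asm, contrast = contrast, correlation = correlation,
    idm = idm, entropy = entropy)
}
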