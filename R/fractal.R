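#' Default box-size series for the fractal grid scan
#'
#' Linear series of box edge lengths: 5 to 575 pixels in 3-pixel
#' increments (191 sizes). Sizes exceeding the shorter image side are
#' dropped at scan time.
#'
#' @param from,to,by series start, end and step in pixels.
#' @return integer vector of box sizes.
#' @export
defaultBoxSizes <- function(from = 5L, to = 575L, by = 3L) {
  as.integer(seq.int(from, to, by))
}

# closed-form OLS of y ~ x with slope SE and r^2
olsFit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  int <- my - slope * mx
  res <- y - int - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  se <- if (n > 2) sqrt(max(sse, 0) / (n - 2) / sxx) else NA_real_
  c(slope = slope, yint = int, r2 = max(min(r2, 1), 0), se = se)
}

countingMode <- function(counting) {
  match(match.arg(counting, c("binary", "differential", "span")),
    c("binary", "differential", "span")) - 1L
}

#' Box-counting grid scan at one grid position
#'
#' Tiles the image with boxes of each size `eps` from a grid anchored at
#' `offset`, visiting complete boxes only; box counts are rescaled to the
#' full image area so that partial edge coverage does not bias the
#' regression. Three counting rules are available:
#' \describe{
#'   \item{`"binary"` (default)}{a box counts 1 if it contains any
#'     non-white pixel (grey level < 255). This measures the geometry of
#'     the stained support, the natural reading for white-filled sliced
#'     images where 255 is background fill.}
#'   \item{`"differential"`}{Sarkar-Chaudhuri differential box counting:
#'     `n_b = floor(max/h) - floor(min/h) + 1` with grey-box height
#'     `h = eps * 256 / min(W, H)`; measures the grey-level surface.}
#'   \item{`"span"`}{`n_b = 1 + (max - min) * spanScale`.}
#' }
#' Each box's mass `sum(255 - v)` (stain-weighted: dark pixels are heavy)
#' is summarised per size by its mean and population SD, feeding the mass
#' dimension and lacunarity.
#'
#' @param img a [GreyImage-class], [SlicedImage-class] or \[0,255\] matrix.
#' @param offset integer `c(dx, dy)` grid anchor shift in pixels.
#' @param boxSizes increasing integer box sizes; sizes larger than the
#'   shorter image side (or leaving no complete box) are dropped.
#' @param counting counting rule, see above.
#' @param spanScale scale for `"span"` counting (default `255 / 256`).
#' @return an object of class `"grid_scan"`: list with `boxSizes`, `N`
#'   (area-corrected box counts), `nBoxes`, `massMean`, `massSD`, `offset`,
#'   and the log-log regression of `N` on `1/eps`: `D` (slope), `yInt`,
#'   `r2`, `slopeSE`.
#' @examples
#' sc <- scanGrid(greyImage(matrix(100L, 64, 64)), boxSizes = c(4L, 8L, 16L))
#' sc$D  # exactly 2 for a constant image
#' @export
scanGrid <- function(img, offset = c(0L, 0L), boxSizes = defaultBoxSizes(),
                     counting = c("binary", "differential", "span"),
                     spanScale = 255 / 256) {
  v <- if (is(img, "GreyImage")) img@pixels else
    if (is(img, "SlicedImage")) img@image@pixels else img
  stopifnot(is.matrix(v))
  storage.mode(v) <- "integer"
  mode <- countingMode(counting)
  W <- nrow(v); H <- ncol(v)
  if (min(W, H) < min(boxSizes))
    stop("image smaller than the smallest box size")
  offset <- as.integer(offset)
  sizes <- sort(unique(as.integer(boxSizes)))
  usable <- sizes[sizes <= min(W - offset[1], H - offset[2])]
  if (length(usable) < length(sizes))
    message(length(sizes) - length(usable),
      " box size(s) exceed the usable image extent and were dropped")
  h <- usable * 256 / min(W, H)
  m <- .boxScanCpp(v, usable, offset[1], offset[2], h, mode, spanScale)
  # rescale complete-box counts to the full image area
  nbx <- (W - offset[1]) %/% usable
  nby <- (H - offset[2]) %/% usable
  N <- m[, "N_raw"] * (W * H) / (nbx * nby * usable^2)
  keep <- is.finite(N) & N > 0
  if (sum(keep) < 3)
    stop("fewer than 3 usable box sizes: regression underdetermined")
  fit <- olsFit(log(1 / usable[keep]), log(N[keep]))
  structure(list(
    boxSizes = usable, N = N, nBoxes = m[, "n_boxes"],
    massMean = m[, "mass_mean"], massSD = m[, "mass_sd"],
    offset = offset, counting = match.arg(counting),
    D = unname(fit["slope"]), yInt = unname(fit["yint"]),
    r2 = unname(fit["r2"]), slopeSE = unname(fit["se"])
  ), class = "grid_scan")
}

#' @export
print.grid_scan <- function(x, ...) {
  cat(sprintf(
    "grid_scan (%s): %d box sizes %d..%d, offset (%d,%d)\n  D = %.4f (SE %.4f), y-int = %.3f, r2 = %.5f\n",
    x$counting, length(x$boxSizes), min(x$boxSizes), max(x$boxSizes),
    x$offset[1], x$offset[2], x$D, x$slopeSE, x$yInt, x$r2))
  invisible(x)
}

#' Names of the 23 monofractal features
#' @return character vector of length 23.
#' @export
fractalFeatureNames <- function() {
  c("d_b", "sd_d_b", "d_b_min", "d_b_max", "d_b_best_r2", "se_d_b", "yint_d_b",
    "d_m", "sd_d_m", "d_m_min", "d_m_max", "d_m_best_r2", "se_d_m", "yint_d_m",
    "d_x_best_r2", "se_d_x", "yint_d_x",
    "lam", "lam_prime", "lam_min", "lam_max", "cv_lam_g", "cv_lam_prime_g")
}

#' The 23 monofractal features over repositioned grids
#'
#' Runs [scanGrid()] at `nGrids` grid positions (the reference offset (0,0)
#' plus seeded pseudo-random offsets within `[0, min(boxSizes))^2`) and
#' summarises:
#' \itemize{
#'   \item box dimension `d_b`: mean of per-grid log-log slopes, with their
#'     SD (`sd_d_b`, dispersion over grids), extrema, the slope of the grid
#'     with highest r2 (`d_b_best_r2`), and the slope SE and intercept of
#'     the regression on the grid-averaged counts (`se_d_b`, `yint_d_b`);
#'   \item mass dimension `d_m` and analogues, from regressions of
#'     `log(mean box mass)` on `log(eps)` (mass is inverted intensity
#'     `255 - v`, so stain-dense boxes are heavy);
#'   \item optimal-cover dimension `d_x_best_r2` with `se_d_x`, `yint_d_x`:
#'     the regression on the per-size minimum count across grids;
#'   \item lacunarity `lambda(eps, g) = (sd/mean)^2` of box masses:
#'     `lam` (mean over sizes at the reference grid), `lam_prime` (mean
#'     over sizes and grids), per-grid-mean extrema `lam_min`/`lam_max`,
#'     and coefficients of variation `cv_lam_g` (over per-grid means) and
#'     `cv_lam_prime_g` (over all size-grid values).
#' }
#'
#' @param img a [GreyImage-class], [SlicedImage-class] or \[0,255\] matrix.
#' @param nGrids number of grid positions (default 12).
#' @param boxSizes box-size series, default [defaultBoxSizes()].
#' @param seed integer seed for the grid offsets; fixed seed gives
#'   identical features.
#' @param counting counting rule, see [scanGrid()].
#' @param spanScale scale for `"span"` counting.
#' @return named numeric vector with the 23 features of
#'   [fractalFeatureNames()]. Undefined values (e.g. mass features of an
#'   all-white image) are `NA`.
#' @export
fractalFeatures <- function(img, nGrids = 12L, boxSizes = defaultBoxSizes(),
                            seed = 1L,
                            counting = c("binary", "differential", "span"),
                            spanScale = 255 / 256) {
  counting <- match.arg(counting)
  emin <- min(boxSizes)
  d <- if (is(img, "GreyImage") || is(img, "SlicedImage")) dim(img) else
    dim(as.matrix(img))
  # trim once so every grid position sees the same size series
  maxOff <- if (nGrids > 1) emin - 1L else 0L
  usable <- boxSizes[boxSizes <= min(d) - maxOff]
  if (length(usable) < length(boxSizes))
    message(length(boxSizes) - length(usable),
      " box size(s) exceed the usable image extent and were dropped")
  if (length(usable) < 3L)
    stop("fewer than 3 usable box sizes: regression underdetermined")
  boxSizes <- usable
  offs <- rbind(c(0L, 0L),
    if (nGrids > 1)
      withr::with_seed(seed, matrix(
        sample.int(emin, 2L * (nGrids - 1L), replace = TRUE) - 1L,
        ncol = 2)))
  scans <- lapply(seq_len(nrow(offs)), function(i)
    tryCatch(
      suppressMessages(scanGrid(img, offs[i, ], boxSizes, counting,
        spanScale)),
      error = function(e) NULL))
  if (any(vapply(scans, is.null, logical(1)))) {
    # degenerate input (e.g. empty stained support under binary counting):
    # every feature is undefined, flagged as NA rather than an error
    out <- rep(NA_real_, 23L)
    names(out) <- fractalFeatureNames()
    return(out)
  }

  slopes <- vapply(scans, `[[`, numeric(1), "D")
  r2s <- vapply(scans, `[[`, numeric(1), "r2")

  # mass regressions per grid: log(mean mass) ~ log(eps)
  massFit <- lapply(scans, function(sc) {
    ok <- is.finite(sc$massMean) & sc$massMean > 0
    if (sum(ok) < 3) return(c(slope = NA_real_, yint = NA_real_,
      r2 = NA_real_, se = NA_real_))
    olsFit(log(sc$boxSizes[ok]), log(sc$massMean[ok]))
  })
  mSlopes <- vapply(massFit, `[`, numeric(1), "slope")
  mR2 <- vapply(massFit, `[`, numeric(1), "r2")

  # grid-averaged regressions (common sizes across grids)
  common <- Reduce(intersect, lapply(scans, `[[`, "boxSizes"))
  Nmat <- vapply(scans, function(sc)
    sc$N[match(common, sc$boxSizes)], numeric(length(common)))
  Mmat <- vapply(scans, function(sc)
    sc$massMean[match(common, sc$boxSizes)], numeric(length(common)))
  nBar <- rowMeans(Nmat)
  okN <- is.finite(nBar) & nBar > 0
  avgFit <- if (sum(okN) >= 3)
    olsFit(log(1 / common[okN]), log(nBar[okN])) else
    c(slope = NA_real_, yint = NA_real_, r2 = NA_real_, se = NA_real_)
  mBar <- rowMeans(Mmat)
  okM <- is.finite(mBar) & mBar > 0
  avgMassFit <- if (sum(okM) >= 3)
    olsFit(log(common[okM]), log(mBar[okM])) else
    c(slope = NA_real_, yint = NA_real_, r2 = NA_real_, se = NA_real_)

  # optimal cover: per-size minimum count across grids
  nMin <- apply(Nmat, 1, min)
  okX <- is.finite(nMin) & nMin > 0
  xFit <- if (sum(okX) >= 3)
    olsFit(log(1 / common[okX]), log(nMin[okX])) else
    c(slope = NA_real_, yint = NA_real_, r2 = NA_real_, se = NA_real_)

  # lacunarity per (size, grid)
  lamList <- lapply(scans, function(sc)
    ifelse(sc$massMean > 0, (sc$massSD / sc$massMean)^2, 0))
  lamGrid <- vapply(lamList, mean, numeric(1))  # per-grid mean over sizes
  lamAll <- unlist(lamList)
  cv <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0 || mean(x) == 0) 0 else stats::sd(x) / mean(x)
  }

  out <- c(
    d_b = mean(slopes), sd_d_b = stats::sd(slopes),
    d_b_min = min(slopes), d_b_max = max(slopes),
    d_b_best_r2 = slopes[which.max(r2s)],
    se_d_b = unname(avgFit["se"]), yint_d_b = unname(avgFit["yint"]),
    d_m = mean(mSlopes), sd_d_m = stats::sd(mSlopes),
    d_m_min = suppressWarnings(min(mSlopes)),
    d_m_max = suppressWarnings(max(mSlopes)),
    d_m_best_r2 = if (all(is.na(mR2))) NA_real_ else
      mSlopes[which.max(mR2)],
    se_d_m = unname(avgMassFit["se"]), yint_d_m = unname(avgMassFit["yint"]),
    d_x_best_r2 = unname(xFit["slope"]),
    se_d_x = unname(xFit["se"]), yint_d_x = unname(xFit["yint"]),
    lam = lamGrid[1], lam_prime = mean(lamAll),
    lam_min = min(lamGrid), lam_max = max(lamGrid),
    cv_lam_g = cv(lamGrid), cv_lam_prime_g = cv(lamAll)
  )
  names(out) <- fractalFeatureNames()
  out
}

#' Sierpinski carpet test image
#'
#' Renders the level-`k` Sierpinski carpet (a classical fractal of
#' box-counting dimension `log 8 / log 3 ~= 1.893`) as a `3^k x 3^k`
#' GreyImage with set pixels 0 (black) and background 255 (white). Used as
#' an analytic fixture for the fractal scan.
#'
#' @param level recursion depth (image side `3^level`).
#' @return a [GreyImage-class].
#' @export
sierpinskiCarpet <- function(level = 6L) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(level)) {
    n <- nrow(m)
    M <- matrix(FALSE, 3 * n, 3 * n)
    for (bi in 0:2) for (bj in 0:2) if (!(bi == 1 && bj == 1))
      M[bi * n + seq_len(n), bj * n + seq_len(n)] <- m
    m <- M
  }
  greyImage(ifelse(m, 0L, 255L))
}
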