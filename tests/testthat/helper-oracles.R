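# Independent brute-force oracles used across the suite. These deliberately
# mirror the definitions, not the implementations: plain double loops.

# 3x3 worked example used by the slicing and first-order tests
workedImage <- function() {
  greyImage(matrix(c(100L, 150L, 170L, 190L, 210L, 230L, 250L, 255L, 160L),
    3, 3))
}

# exhaustive pairwise AUC: mean over pos x neg pairs of
# [s_p > s_n] + 0.5 [s_p == s_n]
pairAuc <- function(scores, outcomes) {
  sp <- scores[outcomes == 1]
  sn <- scores[outcomes == 0]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# naive GLCM features by double loops over the matrix
naiveGlcmFeatures <- function(p) {
  n <- nrow(p)
  asm <- 0; contrast <- 0; idm <- 0; entropy <- 0
  mux <- 0; muy <- 0
  for (i in 1:n) for (j in 1:n) {
    mux <- mux + (i - 1) * p[i, j]
    muy <- muy + (j - 1) * p[i, j]
  }
  sx2 <- 0; sy2 <- 0; cov <- 0
  for (i in 1:n) for (j in 1:n) {
    v <- p[i, j]
    asm <- asm + v^2
    contrast <- contrast + ((i - 1) - (j - 1))^2 * v
    idm <- idm + v / (1 + ((i - 1) - (j - 1))^2)
    if (v > 0) entropy <- entropy - v * log(v)
    sx2 <- sx2 + ((i - 1) - mux)^2 * v
    sy2 <- sy2 + ((j - 1) - muy)^2 * v
    cov <- cov + ((i - 1) - mux) * ((j - 1) - muy) * v
  }
  corr <- if (sx2 * sy2 == 0) NA_real_ else cov / sqrt(sx2 * sy2)
  c(asm = asm, contrast = contrast, correlation = corr, idm = idm,
    entropy = entropy)
}

# naive complete-box grid scan: per-box min/max/mass by explicit loops
naiveBoxScan <- function(px, eps, dx = 0, dy = 0,
                         counting = c("binary", "differential")) {
  counting <- match.arg(counting)
  W <- nrow(px); H <- ncol(px)
  nbx <- (W - dx) %/% eps; nby <- (H - dy) %/% eps
  h <- eps * 256 / min(W, H)
  Nraw <- 0; masses <- numeric(0)
  for (bx in seq_len(nbx) - 1) for (by in seq_len(nby) - 1) {
    block <- px[dx + bx * eps + 1:eps, dy + by * eps + 1:eps]
    Nraw <- Nraw + if (counting == "binary") as.numeric(any(block < 255)) else
      floor(max(block) / h) - floor(min(block) / h) + 1
    masses <- c(masses, sum(255 - block))
  }
  list(Nraw = Nraw, Ncorr = Nraw * W * H / (nbx * nby * eps^2),
    massMean = mean(masses),
    massSD = sqrt(mean((masses - mean(masses))^2)))
}

# population skewness / excess kurtosis by the direct moment formulas
naiveMoments <- function(v) {
  m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3); m4 <- mean((v - m)^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# forward Beer-Lambert mixing of two stains at given per-pixel densities;
# quantize = TRUE rounds to 8-bit like a real camera would
mixStains <- function(d1, d2, stains = defaultStainVectors(),
                      quantize = FALSE) {
  n <- length(d1)
  od <- outer(d1, stains[1, ]) + outer(d2, stains[2, ])
  I <- 255 * 10^(-od)
  if (quantize) I <- round(I)
  arr <- array(0, dim = c(n, 1, 3))
  for (k in 1:3) arr[, 1, k] <- pmin(pmax(I[, k], 0), 255)
  class(arr) <- "rgb_raster"
  arr
}
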