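test_that("AUC: perfect separation, symmetry with ties, pair-count oracle", {
  expect_equal(rocAuc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(c(1, 2, 1, 2), c(1, 1, 0, 0))$auc, 0.5)
  set.seed(51)
  for (i in 1:20) {
    sc <- sample(1:6, 10, replace = TRUE) + round(runif(10), 2)
    oc <- c(rep(1, 4), rep(0, 6))
    expect_equal(rocAuc(sc, oc)$auc, pairAuc(sc, oc))
  }
})

test_that("AUC direction is fixed: inverted markers give AUC below 0.5", {
  r <- rocAuc(c(1, 2, 9, 10), c(1, 1, 0, 0))
  expect_equal(r$auc, 0)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "positive and")
})

test_that("DeLong CI brackets the AUC and p is calibrated against pROC", {
  set.seed(52)
  sc <- c(rnorm(30, 1), rnorm(40))
  oc <- c(rep(1, 30), rep(0, 40))
  r <- rocAuc(sc, oc)
  expect_true(r$ci_lo <= r$auc && r$auc <= r$ci_hi)
  ref <- pROC::roc(oc, sc, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("foldAuc reflects below 0.5 and is invariant to reflection", {
  expect_equal(foldAuc(0.34), 0.66)
  expect_equal(foldAuc(0.5), 0.5)
  expect_equal(foldAuc(0.77), 0.77)
  a <- seq(0, 1, by = 0.05)
  expect_equal(foldAuc(a), foldAuc(1 - a))
  expect_error(foldAuc(1.2), "must lie")
})

test_that("bootstrap validation: separable data stay high, same seed repeats", {
  sc <- c(rnorm(20, 6), rnorm(20))
  oc <- c(rep(1, 20), rep(0, 20))
  b1 <- bootstrapValidate(sc, oc, nResamples = 200, seed = 5)
  expect_gte(b1$auc_corrected, 0.95)
  b2 <- bootstrapValidate(sc, oc, nResamples = 200, seed = 5)
  expect_identical(b1, b2)
})

test_that("bootstrap validation under the null is centred at 0.5", {
  set.seed(53)
  sc <- rnorm(100)
  oc <- rbinom(100, 1, 0.3)
  b <- bootstrapValidate(sc, oc, nResamples = 1000, seed = 9)
  expect_lt(abs(b$auc_corrected - 0.5), 0.06)
})

test_that("optimal cutoff reproduces the hand-computed 2x2 chi-square", {
  r <- optimalCutoff(c(1, 1, 1, 9, 9, 9, 1, 9),
    c(0, 0, 0, 1, 1, 1, 0, 1))
  expect_equal(r$cutoff, 5)
  expect_equal(r$chi2, 8)   # perfect 4/4 split, n = 8
  r6 <- optimalCutoff(c(1, 1, 1, 9, 9, 9, 2, 8), c(0, 0, 0, 1, 1, 1, 0, 1))
  expect_equal(r6$direction, "high")
})

test_that("cutoff search equals the brute-force maximum over candidates", {
  set.seed(54)
  sc <- rnorm(40)
  oc <- rbinom(40, 1, 0.4)
  r <- optimalCutoff(sc, oc)
  q <- quantile(sc, c(0.1, 0.9), names = FALSE)
  u <- sort(unique(sc))
  mids <- (u[-1] + u[-length(u)]) / 2
  mids <- mids[mids >= q[1] & mids <= q[2]]
  brute <- max(vapply(mids, function(ct) {
    suppressWarnings(chisq.test(table(sc > ct, oc), correct = FALSE))$statistic
  }, numeric(1)))
  expect_equal(r$chi2, unname(brute))
  rflip <- optimalCutoff(-sc, oc)
  expect_equal(rflip$chi2, r$chi2)
  expect_false(identical(rflip$direction, r$direction))
})

test_that("degenerate cutoff inputs error clearly", {
  expect_error(optimalCutoff(rep(1, 10), rbinom(10, 1, 0.5)), "identical")
  expect_error(optimalCutoff(1:6, rep(0:1, 3)), "at least 8")
})

test_that("spearman matrix: identical, complementary and formula checks", {
  a <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 1)
  m <- spearmanMatrix(cbind(x = a, y = a, z = 1 - a))
  expect_equal(m$rho["x", "y"], 1)
  expect_equal(m$rho["x", "z"], -1)
  set.seed(55)
  b <- rbinom(10, 1, 0.5)
  m2 <- spearmanMatrix(cbind(a = a, b = b))
  expect_equal(m2$rho["a", "b"], unname(cor(a, b, method = "spearman")),
    tolerance = 1e-12)
  m3 <- spearmanMatrix(cbind(a = a, c = rep(1, 10)))
  expect_true(is.na(m3$rho["a", "c"]))
})

test_that("stepwise keeps a strong predictor, drops noise and collinear copies", {
  set.seed(56)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
  d <- data.frame(outcome = y, strong = x, noise1 = rnorm(n),
    noise2 = rnorm(n), noise3 = rnorm(n))
  m <- stepwiseLogistic(d, "outcome", c("strong", "noise1", "noise2", "noise3"))
  expect_identical(m$terms$term, "strong")
  expect_true(all(m$terms$p <= 0.05))
  expect_gt(m$terms$hr, 1)

  # all-noise: empty model at this fixed seed
  m0 <- stepwiseLogistic(d, "outcome", c("noise1", "noise2", "noise3"))
  expect_identical(nrow(m0$terms), 0L)

  # exact collinear duplicate: exactly one of the pair is retained
  d$strong_copy <- d$strong
  m2 <- stepwiseLogistic(d, "outcome", c("strong", "strong_copy"))
  expect_identical(nrow(m2$terms), 1L)
  expect_true(m2$terms$term %in% c("strong", "strong_copy"))
})

test_that("perfect separation is flagged and excluded, not fatal", {
  d <- data.frame(outcome = rep(0:1, each = 20),
    sep = c(rnorm(20, -10), rnorm(20, 10)), ok = rnorm(40))
  expect_warning(m <- stepwiseLogistic(d, "outcome", c("sep", "ok")),
    "separation")
  expect_true("sep" %in% m$excluded)
})

test_that("range summary implements the improvement rule", {
  tab <- data.frame(
    feature = c("f1", "f1", "f2", "f2"),
    family = "glcm",
    range_label = c("0-255", "160-180", "0-255", "160-180"),
    auc = c(0.60, 0.70, 0.55, 0.40),
    p = c(0.20, 0.01, 0.30, 0.20))
  rs <- rangeSummary(tab)
  row <- rs[rs$range_label == "160-180", ]
  # only f1 is significant: improvement = |0.70-0.5| - |0.60-0.5| = 0.10
  expect_equal(row$improvement_glcm, 0.10)
  expect_equal(row$improvement_total, 0.10)
  expect_equal(row$mean_folded_auc, mean(c(0.70, 0.60)))
  # significant but worse features clip at zero
  tab2 <- tab
  tab2$auc[2] <- 0.52; tab2$p[2] <- 0.04
  expect_equal(rangeSummary(tab2)$improvement_glcm[2], 0)
})

test_that("sample size decreases with effect size and matches a power-curve search", {
  n1 <- rocSampleSize(aucAlt = 0.67)$n_pos
  n2 <- rocSampleSize(aucAlt = 0.75)$n_pos
  n3 <- rocSampleSize(aucAlt = 0.90)$n_pos
  expect_true(n1 > n2 && n2 > n3)
  expect_error(rocSampleSize(aucAlt = 0.5), "undetectable")

  # independent direct power-curve search at aucAlt 0.75, ratio 1
  vHM <- function(A, np, nn) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    (A * (1 - A) + (np - 1) * (q1 - A^2) + (nn - 1) * (q2 - A^2)) / (np * nn)
  }
  power <- function(n) {
    crit <- qnorm(0.975) * sqrt(vHM(0.5, n, n))
    pnorm((0.25 - crit) / sqrt(vHM(0.75, n, n)))
  }
  ns <- 2:500
  oracle <- ns[which(vapply(ns, power, numeric(1)) >= 0.8)[1]]
  expect_identical(rocSampleSize(aucAlt = 0.75, ratio = 1)$n_pos, oracle)
})
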