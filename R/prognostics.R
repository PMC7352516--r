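#' ROC analysis of one continuous feature against a binary endpoint
#'
#' The AUC is the Mann-Whitney estimator (probability that a random
#' positive scores above a random negative, ties counted half), computed
#' with a fixed direction so that values below 0.5 indicate association
#' with the negative class; see [foldAuc()] for averaging. The 95%
#' confidence interval and the two-sided p-value against AUC = 0.5 use the
#' DeLong variance.
#'
#' @param scores numeric feature values; `NA`s are dropped pairwise with
#'   their outcomes.
#' @param outcomes binary endpoint (0/1 or logical), 1 = event (e.g.
#'   metastasis occurrence).
#' @param conf.level confidence level for the interval.
#' @return object of class `"roc_result"`: list with `auc`, `ci_lo`,
#'   `ci_hi`, `p`, `n_pos`, `n_neg`.
#' @examples
#' rocAuc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc  # 1: perfect separation
#' @export
rocAuc <- function(scores, outcomes, conf.level = 0.95) {
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- as.numeric(scores[keep])
  outcomes <- as.integer(outcomes[keep])
  if (!all(outcomes %in% 0:1)) stop("outcomes must be binary 0/1")
  nPos <- sum(outcomes == 1L); nNeg <- sum(outcomes == 0L)
  if (nPos < 1L || nNeg < 1L)
    stop("need at least one positive and one negative outcome")
  r <- rank(scores)
  auc <- (sum(r[outcomes == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  if (nPos >= 2L && nNeg >= 2L && stats::var(scores) > 0) {
    ro <- pROC::roc(outcomes, scores, direction = "<", levels = c(0, 1),
      quiet = TRUE)
    v <- suppressWarnings(pROC::var(ro, method = "delong"))
    ci <- suppressWarnings(as.numeric(pROC::ci.auc(ro,
      conf.level = conf.level, method = "delong")))
    p <- if (v > 0) 2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v)) else
      if (auc == 0.5) 1 else 0
    ciLo <- ci[1]; ciHi <- ci[3]
  } else {
    ciLo <- ciHi <- p <- NA_real_
  }
  structure(list(auc = auc, ci_lo = ciLo, ci_hi = ciHi, p = p,
    n_pos = nPos, n_neg = nNeg), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), p = %.4g; %d pos / %d neg\n",
    x$auc, x$ci_lo, x$ci_hi, x$p, x$n_pos, x$n_neg))
  invisible(x)
}

#' Fold an AUC into the 0.5-1 range
#'
#' AUC values below 0.5 indicate association with the opposite class;
#' for averaging across features they are reflected: `max(a, 1 - a)`
#' (so 0.34 folds to 0.66).
#'
#' @param a AUC value(s) in \[0, 1\].
#' @return folded value(s) in \[0.5, 1\].
#' @export
foldAuc <- function(a) {
  if (any(a < 0 | a > 1, na.rm = TRUE)) stop("AUC must lie in [0, 1]")
  pmax(a, 1 - a)
}

#' Bootstrap internal validation of an AUC
#'
#' Corrects the apparent (direction-folded) AUC for the optimism of
#' choosing the scoring direction on the same data. For each of
#' `nResamples` patient-level resamples with replacement, the folded AUC on
#' the resample is compared with the AUC the resample-derived direction
#' achieves on the original data; the mean difference is the optimism, and
#' `corrected = apparent - optimism`. Resamples with a single outcome class
#' are redrawn (count reported). The percentile interval of the bootstrap
#' AUCs is returned.
#'
#' @param scores,outcomes as in [rocAuc()].
#' @param nResamples bootstrap resamples (default 1000).
#' @param seed integer seed; fixed seed gives identical output.
#' @param conf.level percentile-interval level.
#' @return list with `auc_apparent` (folded), `optimism`, `auc_corrected`,
#'   `ci_lo`, `ci_hi` (percentile), `n_resamples`, `n_redrawn`.
#' @export
bootstrapValidate <- function(scores, outcomes, nResamples = 1000L,
                              seed = 1L, conf.level = 0.95) {
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- as.numeric(scores[keep]); outcomes <- as.integer(outcomes[keep])
  n <- length(scores)
  baseAuc <- function(s, o) {
    np <- sum(o == 1L); nn <- sum(o == 0L)
    r <- rank(s)
    (sum(r[o == 1L]) - np * (np + 1) / 2) / (np * nn)
  }
  a0 <- baseAuc(scores, outcomes)
  apparent <- max(a0, 1 - a0)
  withr::with_seed(seed, {
    nRedrawn <- 0L
    optim <- numeric(nResamples)
    boots <- numeric(nResamples)
    for (b in seq_len(nResamples)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(outcomes[idx])) == 2L) break
        nRedrawn <- nRedrawn + 1L
      }
      ab <- baseAuc(scores[idx], outcomes[idx])
      dirb <- if (ab >= 0.5) 1 else -1
      abFold <- max(ab, 1 - ab)
      aOrig <- if (dirb > 0) a0 else 1 - a0
      optim[b] <- abFold - aOrig
      boots[b] <- abFold
    }
  })
  alpha <- (1 - conf.level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  list(auc_apparent = apparent, optimism = mean(optim),
    auc_corrected = apparent - mean(optim),
    ci_lo = ci[1], ci_hi = ci[2],
    n_resamples = nResamples, n_redrawn = nRedrawn)
}

#' Optimal dichotomising cutoff by chi-square maximisation
#'
#' Maximally selected chi-square statistics: an exhaustive scan of the midpoints
#' between consecutive sorted unique score values, restricted to the
#' 10th-90th percentile window of the scores, choosing the cutoff that
#' maximises the (uncorrected) 2x2 chi-square statistic against the
#' outcome. Ties are broken towards the smaller cutoff. The
#' Miller-Siegmund minimum-p correction for the maximally selected
#' statistic is available via `correct = TRUE` (reported as `p_corrected`;
#' the selected cutoff is unchanged).
#'
#' @param scores,outcomes as in [rocAuc()]; at least 8 patients.
#' @param window percentile window restricting candidate cutoffs.
#' @param correct apply the Miller-Siegmund correction to the p-value.
#' @return object of class `"cutoff_result"`: list with `cutoff`, `chi2`,
#'   `p`, `n_low`, `n_high`, `direction` (`"high"` if the group above the
#'   cutoff has the higher event rate), and `p_corrected` if requested.
#' @export
optimalCutoff <- function(scores, outcomes, window = c(0.10, 0.90),
                          correct = FALSE) {
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- as.numeric(scores[keep]); outcomes <- as.integer(outcomes[keep])
  n <- length(scores)
  if (n < 8L) stop("need at least 8 patients")
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("all scores identical: no cutoff exists")
  mid <- (u[-1] + u[-length(u)]) / 2
  q <- stats::quantile(scores, window, names = FALSE)
  cand <- mid[mid >= q[1] & mid <= q[2]]
  if (length(cand) == 0L) cand <- mid
  npos <- sum(outcomes)
  chi2 <- vapply(cand, function(ct) {
    hi <- scores > ct
    a <- sum(outcomes[hi]); b <- sum(hi) - a
    c0 <- npos - a; d <- n - sum(hi) - c0
    num <- (a * d - b * c0)^2 * n
    den <- (a + b) * (c0 + d) * (a + c0) * (b + d)
    if (den == 0) 0 else num / den
  }, numeric(1))
  best <- which.max(chi2) # which.max takes the first (smallest) on ties
  ct <- cand[best]
  hi <- scores > ct
  p <- stats::pchisq(chi2[best], df = 1, lower.tail = FALSE)
  out <- list(cutoff = ct, chi2 = chi2[best], p = p,
    n_low = sum(!hi), n_high = sum(hi),
    direction = if (mean(outcomes[hi]) >= mean(outcomes[!hi])) "high" else "low")
  if (correct) {
    # Miller-Siegmund min-p correction at the scanned window
    eps <- window[1]
    z <- sqrt(out$chi2)
    phi <- stats::dnorm(z)
    loge <- log((1 - eps)^2 / eps^2)
    pCorr <- phi * (z - 1 / z) * loge + 4 * phi / z
    out$p_corrected <- min(1, max(pCorr, p))
  }
  class(out) <- "cutoff_result"
  out
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "cutoff = %.4g (chi2 = %.3f, p = %.4g); %d low / %d high, high-risk side: %s\n",
    x$cutoff, x$chi2, x$p, x$n_low, x$n_high, x$direction))
  invisible(x)
}

#' Spearman correlation matrix of categorised classifiers
#'
#' Pairwise Spearman rank correlations (with p-values) between dichotomised
#' 0/1 classifiers, used to assess redundancy between prognostic features.
#' Zero-variance classifiers give `NA` rows/columns.
#'
#' @param classifiers matrix or data.frame, one column per 0/1 classifier.
#' @return list with matrices `rho` and `p` (diagonal rho 1, p `NA`).
#' @export
spearmanMatrix <- function(classifiers) {
  X <- as.matrix(classifiers)
  if (nrow(X) < 3L) stop("need at least 3 patients")
  k <- ncol(X)
  rho <- p <- matrix(NA_real_, k, k,
    dimnames = list(colnames(X), colnames(X)))
  diag(rho) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    xi <- X[, i]; xj <- X[, j]
    ok <- !is.na(xi) & !is.na(xj)
    if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(xi[ok], xj[ok], method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p)
}

# likelihood-ratio p of adding/removing one term
lrtP <- function(fit0, fit1) {
  df <- fit0$df.residual - fit1$df.residual
  if (is.na(df) || df <= 0) return(1) # aliased/collinear term adds nothing
  stats::pchisq(max(fit0$deviance - fit1$deviance, 0), df = df,
    lower.tail = FALSE)
}

#' Stepwise binary logistic regression
#'
#' Forward selection with backward elimination on likelihood-ratio
#' p-values: at each step the candidate with the smallest addition p-value
#' enters if `p <= entry`, then retained terms with removal `p > remain`
#' are dropped, until the model is stable. Continuous feature values are
#' used as supplied. Candidates producing (quasi-)perfect separation are
#' flagged and excluded with a warning. For each retained term the
#' coefficient, the hazard ratio `HR = exp(coef)`, its Wald 95% CI and the
#' likelihood-ratio p-value are reported.
#'
#' @param data data.frame containing `outcome` and the candidate columns.
#' @param outcome name of the binary outcome column.
#' @param candidates character vector of candidate term names (typically
#'   pre-filtered to univariately significant features).
#' @param entry,remain entry and remain p-value criteria (default 0.05).
#' @return object of class `"stepwise_model"`: list with `terms`
#'   (data.frame: term, coef, hr, ci_lo, ci_hi, p), `excluded` (separation
#'   flags), and the final `fit`.
#' @export
stepwiseLogistic <- function(data, outcome, candidates,
                             entry = 0.05, remain = 0.05) {
  stopifnot(outcome %in% names(data), all(candidates %in% names(data)))
  y <- data[[outcome]]
  if (!all(stats::na.omit(y) %in% 0:1)) stop("outcome must be binary 0/1")
  # work on syntactic column names (feature columns carry '-' and '.'),
  # mapping back for reporting
  data <- data[, c(outcome, candidates), drop = FALSE]
  origNames <- candidates
  safe <- make.names(c(outcome, candidates), unique = TRUE)
  names(data) <- safe
  outcome <- safe[1]
  candidates <- safe[-1]
  unsafeName <- stats::setNames(origNames, candidates)
  sep <- character(0)
  fitWith <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1",
      response = outcome)
    stats::glm(fml, family = stats::binomial(), data = data)
  }
  sdx <- vapply(data[candidates], function(v)
    stats::sd(as.numeric(v), na.rm = TRUE), numeric(1))
  isSeparated <- function(fit) {
    # scale-invariant: a diverged coefficient moves the linear predictor by
    # tens of log-odds per predictor SD, and fitted probabilities pin at 0/1
    w <- fit$fitted.values
    cf <- stats::coef(fit)[-1]
    std <- abs(cf) * sdx[names(cf)]
    any(std > 30, na.rm = TRUE) || all(w > 0.9999 | w < 1e-4)
  }
  current <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, c(current, sep))
    if (length(pool)) {
      fit0 <- fitWith(current)
      ps <- vapply(pool, function(tm) {
        fit1 <- tryCatch(suppressWarnings(fitWith(c(current, tm))),
          error = function(e) NULL)
        if (is.null(fit1)) return(NA_real_)
        if (isSeparated(fit1)) return(-1) # flag
        lrtP(fit0, fit1)
      }, numeric(1))
      newSep <- pool[!is.na(ps) & ps < 0]
      if (length(newSep)) {
        warning("excluded for (quasi-)separation: ",
          paste(unsafeName[newSep], collapse = ", "))
        sep <- c(sep, newSep)
        ps[ps < 0] <- NA
      }
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) <= entry) {
        current <- c(current, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward pass
    repeat {
      if (length(current) == 0L) break
      fit1 <- suppressWarnings(fitWith(current))
      ps <- vapply(current, function(tm) {
        lrtP(suppressWarnings(fitWith(setdiff(current, tm))), fit1)
      }, numeric(1))
      if (max(ps) > remain) {
        current <- setdiff(current, current[which.max(ps)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- suppressWarnings(fitWith(current))
  terms <- if (length(current)) {
    cf <- stats::coef(fit)[current]
    se <- sqrt(diag(stats::vcov(fit)))[current]
    ps <- vapply(current, function(tm)
      lrtP(suppressWarnings(fitWith(setdiff(current, tm))), fit), numeric(1))
    data.frame(term = unname(unsafeName[current]), coef = unname(cf),
      hr = exp(unname(cf)),
      ci_lo = exp(unname(cf - 1.96 * se)),
      ci_hi = exp(unname(cf + 1.96 * se)),
      p = unname(ps), row.names = NULL)
  } else {
    data.frame(term = character(0), coef = numeric(0), hr = numeric(0),
      ci_lo = numeric(0), ci_hi = numeric(0), p = numeric(0))
  }
  structure(list(terms = terms, excluded = unname(unsafeName[sep]),
    fit = fit), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (nrow(x$terms) == 0) {
    cat("stepwise logistic model: empty (no term met the entry criterion)\n")
  } else {
    cat("stepwise logistic model:\n")
    print(x$terms, digits = 3)
  }
  if (length(x$excluded))
    cat("excluded (separation):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Range-level AUC summaries (mean folded AUC and improvement sums)
#'
#' For each intensity range: the mean of the folded AUCs over all features
#' evaluated in that range, and, per feature family and in total, the sum
#' of prognostically significant AUC improvements relative to the original
#' images. The improvement of one feature is
#' `max(0, |AUC_range - 0.5| - |AUC_original - 0.5|)`, counted only when
#' the feature is significant (`p <= alpha`) in that range and only when an
#' original-image AUC exists for the feature.
#'
#' @param aucTable data.frame with columns `feature`, `family`,
#'   `range_label`, `auc`, `p` (long format, one row per feature x range).
#' @param originalLabel the `range_label` holding the original-image AUCs
#'   (default `"0-255"`).
#' @param alpha significance level for counting improvements.
#' @return data.frame, one row per range: `range_label`,
#'   `mean_folded_auc`, one `improvement_<family>` column per family, and
#'   `improvement_total`.
#' @export
rangeSummary <- function(aucTable, originalLabel = "0-255", alpha = 0.05) {
  need <- c("feature", "family", "range_label", "auc", "p")
  stopifnot(all(need %in% names(aucTable)))
  orig <- aucTable[aucTable$range_label == originalLabel, ]
  if (nrow(orig) == 0) stop("no rows with the original range label '",
    originalLabel, "'")
  origAuc <- stats::setNames(orig$auc, orig$feature)
  families <- unique(aucTable$family)
  ranges <- unique(aucTable$range_label)
  rows <- lapply(ranges, function(rl) {
    sub <- aucTable[aucTable$range_label == rl, ]
    mfa <- mean(foldAuc(sub$auc[!is.na(sub$auc)]))
    imp <- vapply(families, function(fam) {
      s <- sub[sub$family == fam & !is.na(sub$auc) & !is.na(sub$p) &
        sub$p <= alpha, ]
      if (nrow(s) == 0) return(0)
      ao <- origAuc[s$feature]
      d <- pmax(0, abs(s$auc - 0.5) - abs(ao - 0.5))
      sum(d[!is.na(d)])
    }, numeric(1))
    out <- data.frame(range_label = rl, mean_folded_auc = mfa)
    for (fam in families) out[[paste0("improvement_", fam)]] <-
      if (rl == originalLabel) NA_real_ else unname(imp[fam])
    out$improvement_total <- if (rl == originalLabel) NA_real_ else sum(imp)
    out
  })
  do.call(rbind, rows)
}

#' ROC sample-size computation (Hanley-McNeil)
#'
#' Minimal number of positive cases (and total patients, given the
#' negative:positive ratio) such that a test of the AUC against
#' `aucNull` at significance `alpha` attains the requested power for a
#' true AUC of `aucAlt`. Uses the Hanley-McNeil variance
#' `V(A) = [A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)] /
#' (n_pos n_neg)` with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, iterating n
#' upward until `z_alpha * sqrt(V(aucNull)) + z_beta * sqrt(V(aucAlt)) <=
#' aucAlt - aucNull`.
#'
#' @param aucAlt expected AUC under the alternative (> `aucNull`).
#' @param aucNull null AUC (default 0.5).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param ratio negative:positive case ratio (default 4).
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return list with `n_pos`, `n_neg`, `n_total`.
#' @export
rocSampleSize <- function(aucAlt = 0.67, aucNull = 0.5, alpha = 0.05,
                          power = 0.80, ratio = 4,
                          alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (aucAlt <= aucNull) stop("aucAlt must exceed aucNull (undetectable effect)")
  if (aucAlt > 1) stop("aucAlt must be at most 1")
  if (ratio < 1) stop("ratio must be >= 1")
  za <- stats::qnorm(1 - alpha / if (alternative == "two.sided") 2 else 1)
  zb <- stats::qnorm(power)
  vHM <- function(A, np, nn) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    (A * (1 - A) + (np - 1) * (q1 - A^2) + (nn - 1) * (q2 - A^2)) / (np * nn)
  }
  delta <- aucAlt - aucNull
  for (n in 2:100000) {
    nn <- ceiling(ratio * n)
    if (za * sqrt(vHM(aucNull, n, nn)) + zb * sqrt(vHM(aucAlt, n, nn)) <= delta)
      return(list(n_pos = n, n_neg = nn, n_total = n + nn))
  }
  stop("no attainable sample size below 100000 positives")
}
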