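#' ROC curve and AUC
#'
#' The AUC equals the all-pairs concordance probability: the probability
#' that a randomly chosen case scores above a randomly chosen control, with
#' ties counting one half. The curve is built by a threshold sweep over the
#' unique scores (predict "case" when score >= threshold).
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary 0/1 labels, both classes present.
#' @return List with `roc` (tibble: `threshold`, `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1), both coordinates non-decreasing) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop_domain("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  tp <- cumsum(yy == 1L); fp <- cumsum(yy == 0L)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each distinct score
  roc <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1))
  list(roc = roc, auc = auc_rank(scores, y))
}

#' Classification accuracy at a probability threshold
#'
#' @param scores Predicted case probabilities.
#' @param labels Binary 0/1 labels.
#' @param threshold Predict case when `score >= threshold` (default 0.5).
#' @return Fraction of donors classified correctly.
#' @export
accuracy <- function(scores, labels, threshold = 0.5) {
  mean(as.integer(scores >= threshold) == as.integer(labels))
}

#' Percentile bootstrap confidence interval for a classification metric
#'
#' Resamples donors with replacement (or whole matched pairs, when
#' `pair_id` is supplied), recomputes the metric on each resample, and
#' returns the percentile interval. Resamples lacking one of the classes
#' are redrawn.
#'
#' @param scores,labels As in [roc_auc()].
#' @param metric `"auc"`, `"accuracy"`, or a `function(scores, labels)`.
#' @param n_boot Number of bootstrap resamples (minimum 1000).
#' @param level Interval coverage level.
#' @param seed Integer seed.
#' @param pair_id Optional pair identifiers; when given, resampling is at
#'   the pair level.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auc", n_boot = 10000,
                         level = 0.95, seed = 1L, pair_id = NULL) {
  if (n_boot < 1000) stop_domain("n_boot must be at least 1000")
  y <- as.integer(labels)
  f <- if (is.function(metric)) {
    metric
  } else if (identical(metric, "auc")) {
    auc_rank
  } else if (identical(metric, "accuracy")) {
    accuracy
  } else {
    stop_domain("metric must be 'auc', 'accuracy', or a function")
  }
  n <- length(scores)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (try in 1:1000) {
        idx <- if (is.null(pair_id)) {
          sample.int(n, n, replace = TRUE)
        } else {
          ids <- unique(pair_id)
          picked <- sample(ids, length(ids), replace = TRUE)
          unlist(lapply(picked, function(p) which(pair_id == p)),
                 use.names = FALSE)
        }
        if (length(unique(y[idx])) == 2) {
          return(f(scores[idx], y[idx]))
        }
      }
      NA_real_
    }, 0)
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop_domain("metric degenerate on all resamples")
  ci <- unname(quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2)))
  c(lo = ci[1], hi = ci[2])
}

# Structural components of the AUC: per-case mean of the case>control
# indicator (ties = 1/2) and the per-control complement.
delong_components <- function(scores, y) {
  x1 <- scores[y == 1L]; x0 <- scores[y == 0L]
  psi <- outer(x1, x0, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), auc = mean(psi))
}

#' DeLong's test for two correlated AUCs
#'
#' Paired, two-sided asymptotic test of equality of the AUCs of two score
#' vectors over the same donors, using the structural-components covariance
#' estimator and a normal reference for the AUC difference.
#'
#' @param scores_a,scores_b Two score vectors over the same donors.
#' @param labels Binary 0/1 labels, both classes present.
#' @return List with `auc_a`, `auc_b`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    stop_domain("score vectors and labels must have equal length")
  }
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop_domain("both classes must be present")
  }
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      return(list(auc_a = ca$auc, auc_b = cb$auc, p = 1))
    }
    abort("zero variance of the AUC difference with unequal AUCs",
          class = "drc_error_internal")
  }
  z <- d / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, p = 2 * pnorm(-abs(z)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities, at
#' fixed margins, of all tables no more probable than the observed one.
#' Used here to compare the correct/incorrect classification counts of two
#' models.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = groups, columns =
#'   (success, failure): table `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop_domain("cell counts must be non-negative integers")
  }
  fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  cor(x, y, method = "spearman")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The p-value is exact (full
#' enumeration) when the combined sample size is at most 12 and there are
#' no ties, and a tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `U` (statistic for `x` vs `y`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fit and compare two competing feature sets
#'
#' Fits the same random-forest configuration (same seed stream) to two
#' candidate feature sets over the same donors, then compares them by
#' DeLong's test on the paired AUCs and by Fisher's exact test on the 2x2
#' table of correct/incorrect classifications at probability threshold 0.5.
#'
#' @param features_a,features_b Two feature tables over the same donors.
#' @param labels Binary 0/1 labels.
#' @param config A [forest_config()].
#' @param label_a,label_b Model names for the report.
#' @return List: `model_a`, `model_b`, `auc_a`, `auc_b`, `delong_p`,
#'   `acc_a`, `acc_b`, `fisher_p`, `scores_a`, `scores_b`.
#' @export
compare_models <- function(features_a, features_b, labels,
                           config = forest_config(),
                           label_a = "model_a", label_b = "model_b") {
  y <- as.integer(labels)
  sa <- rf_fit_predict(features_a, y, config)
  sb <- rf_fit_predict(features_b, y, config)
  dl <- delong_test(sa, sb, y)
  ca <- sum((sa >= 0.5) == (y == 1L)); wa <- length(y) - ca
  cb <- sum((sb >= 0.5) == (y == 1L)); wb <- length(y) - cb
  list(model_a = label_a, model_b = label_b,
       auc_a = dl$auc_a, auc_b = dl$auc_b, delong_p = dl$p,
       acc_a = ca / length(y), acc_b = cb / length(y),
       fisher_p = fisher_exact(ca, wa, cb, wb),
       scores_a = sa, scores_b = sb)
}
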