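test_that("ROC/AUC match the all-pairs concordance oracle", {
  # frozen examples
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)

  set.seed(200)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    ra <- roc_auc(s, y)
    expect_identical(ra$auc, auc_bruteforce(s, y))
    # curve contract
    expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
    expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
    expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
    expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), class = "drc_error_domain")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(201)
  s <- rnorm(40); y <- rep(0:1, 20)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(2 * s - 7, y)$auc, a0)
  expect_equal(roc_auc(atan(s), y)$auc, a0)
})

test_that("accuracy counts thresholded agreement", {
  expect_equal(accuracy(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(accuracy(c(0.1, 0.2, 0.9), c(1, 1, 0)), 0)
  expect_equal(accuracy(c(0.1, 0.6, 0.35, 0.8), c(0, 0, 1, 1)), 0.5)
  # accuracy + error rate = 1 exactly
  set.seed(202)
  s <- runif(31); y <- sample(0:1, 31, replace = TRUE, prob = c(0.4, 0.6))
  expect_identical(accuracy(s, y) + mean((s >= 0.5) != (y == 1)), 1)
})

test_that("Fisher's exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(3, 0, 2, 0), 1)  # zero margin: one table only
  expect_error(fisher_exact(-1, 1, 1, 1), class = "drc_error_domain")
})

test_that("Mann-Whitney U matches enumeration and its symmetries", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  # same multiset in both samples: maximal overlap, p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # swapping samples reflects U and preserves p
  x <- c(0.3, 1.9, 2.2, 5); y <- c(0.7, 1.1, 4)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$U + b$U, length(x) * length(y))
  expect_equal(a$p, b$p)
})

test_that("Spearman correlation is the rank Pearson", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 7, 10)), 1)
  expect_equal(spearman_cor(1:5, -(1:5)^3), -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
})

test_that("DeLong test: identical scores give p = 1, oracle agreement", {
  set.seed(203)
  y <- rep(0:1, 25)
  s <- runif(50)
  r <- delong_test(s, s, y)
  expect_equal(r$p, 1)
  expect_equal(r$auc_a, r$auc_b)

  # cross-check p against the reference structural-components implementation
  skip_if_not_installed("pROC")
  for (i in 1:20) {
    sa <- runif(50); sb <- 0.5 * (y + runif(50))
    mine <- delong_test(sa, sb, y)
    ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                          pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("bootstrap CI honours its contracts", {
  y <- rep(c(1, 0), each = 10)
  s <- as.numeric(y)            # perfectly separated, accuracy constant
  ci <- bootstrap_ci(s, y, "accuracy", n_boot = 1000, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  set.seed(204)
  s2 <- y + rnorm(20, 0, 0.8)
  ci2 <- bootstrap_ci(s2, y, "auc", n_boot = 1000, seed = 2)
  point <- roc_auc(s2, y)$auc
  expect_lte(ci2[["lo"]], point)
  expect_gte(ci2[["hi"]], point)
  expect_error(bootstrap_ci(s2, y, "auc", n_boot = 10), class = "drc_error_domain")

  # deterministic given seed; pair-level resampling is available
  expect_identical(bootstrap_ci(s2, y, "auc", 1000, seed = 3),
                   bootstrap_ci(s2, y, "auc", 1000, seed = 3))
  pid <- rep(1:10, 2)
  ci_pair <- bootstrap_ci(s2, y, "auc", 1000, seed = 3, pair_id = pid)
  expect_true(ci_pair[["lo"]] <= ci_pair[["hi"]])
})

test_that("bootstrap CI width shrinks with sample size", {
  width <- function(n, seed) {
    set.seed(seed)
    y <- rep(0:1, n / 2)
    s <- y + rnorm(n)
    ci <- bootstrap_ci(s, y, "auc", n_boot = 1000, seed = seed)
    ci[["hi"]] - ci[["lo"]]
  }
  w100 <- vapply(1:5, function(s) width(100, s), 0)
  w400 <- vapply(1:5, function(s) width(400, s + 50), 0)
  expect_lt(median(w400), median(w100))
})

test_that("random forest probabilities are honest, seeded and validated", {
  set.seed(205)
  y <- rep(0:1, each = 20)
  feats <- tibble::tibble(x = y * 2 + runif(40, 0, 0.5))  # perfect separator
  cfg <- forest_config(n_trees = 200, seed = 42)
  p <- rf_fit_predict(feats, y, cfg)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(roc_auc(p, y)$auc, 1.0)
  expect_identical(p, rf_fit_predict(feats, y, cfg))

  # permuted labels leave no signal
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    yp <- sample(y)
    roc_auc(rf_fit_predict(feats, yp, forest_config(n_trees = 100, seed = s)),
            yp)$auc
  }, 0)
  expect_true(all(aucs > 0.25 & aucs < 0.75))

  expect_error(rf_fit_predict(feats, rep(1, 40), cfg), class = "drc_error_domain")
  expect_error(forest_config(n_trees = 10), class = "drc_error_config")
  # in-sample and k-fold modes stay on contract
  for (mode in c("insample", "kfold")) {
    pm <- rf_fit_predict(feats, y, forest_config(n_trees = 100, mode = mode,
                                                 seed = 1))
    expect_length(pm, 40)
    expect_true(all(pm >= 0 & pm <= 1))
  }
})

test_that("model comparison reports paired tests on a shared seed stream", {
  set.seed(206)
  y <- rep(0:1, each = 30)
  informative <- tibble::tibble(f = y + rnorm(60, 0, 0.4),
                                age = rnorm(60, 55, 8))
  age_only <- informative["age"]
  cfg <- forest_config(n_trees = 200, seed = 5)
  cmp <- compare_models(informative, age_only, y, cfg)
  expect_true(cmp$delong_p >= 0 && cmp$delong_p <= 1)
  expect_true(cmp$fisher_p >= 0 && cmp$fisher_p <= 1)
  expect_gt(cmp$auc_a, cmp$auc_b)

  # identical feature sets: no difference to detect
  same <- compare_models(age_only, age_only, y, cfg)
  expect_equal(same$delong_p, 1)
  expect_equal(same$fisher_p, 1)
  expect_equal(same$auc_a, same$auc_b)
})
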