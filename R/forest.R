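#' Random-forest configuration
#'
#' @param n_trees Number of trees (minimum 50, so that every donor is
#'   out-of-bag for some trees with overwhelming probability).
#' @param mtry_rule Features tried per split: `"sqrt"` (default) or an
#'   integer count.
#' @param sample_fraction Fraction of donors drawn (with replacement) per
#'   tree.
#' @param mode Evaluation mode for predicted probabilities: `"oob"`
#'   (out-of-bag, default — each donor predicted only by trees that did not
#'   see it), `"insample"`, or `"kfold"`.
#' @param k Folds when `mode = "kfold"`.
#' @param seed Integer seed.
#' @return A validated `forest_config` list.
#' @export
forest_config <- function(n_trees = 500, mtry_rule = "sqrt",
                          sample_fraction = 1, mode = c("oob", "insample", "kfold"),
                          k = 5, seed = 1L) {
  mode <- match.arg(mode)
  if (n_trees < 50) stop_config("n_trees must be at least 50")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop_config("sample_fraction must be in (0, 1]")
  }
  structure(list(n_trees = n_trees, mtry_rule = mtry_rule,
                 sample_fraction = sample_fraction, mode = mode, k = k,
                 seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(rule, p) {
  if (identical(rule, "sqrt")) max(1L, floor(sqrt(p))) else min(p, as.integer(rule))
}

#' Fit a random forest and return per-donor case probabilities
#'
#' Bootstrap-aggregated classification trees with feature randomness at each
#' split; the predicted case probability of a donor averages the votes of
#' the relevant trees. In `"oob"` mode (the default) each donor's
#' probability averages only trees whose bootstrap sample excluded that
#' donor, giving an honest estimate without a held-out set; `"insample"`
#' predicts from all trees; `"kfold"` cross-fits.
#'
#' @param features Numeric feature tibble/data frame (1+ columns, no
#'   missing values).
#' @param labels Binary 0/1 labels with at least two donors per class.
#' @param config A [forest_config()].
#' @return Numeric vector of case probabilities, one per donor, in `[0, 1]`.
#' @export
rf_fit_predict <- function(features, labels, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  features <- tibble::as_tibble(features)
  y <- as.integer(labels)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop_domain("need at least two donors per class")
  }
  if (anyNA(features)) stop_domain("feature table contains missing values")
  dat <- data.frame(features, .label = factor(y, levels = c(0, 1)),
                    check.names = FALSE)
  mtry <- resolve_mtry(config$mtry_rule, ncol(features))
  fit_one <- function(train, seed_off) {
    ranger::ranger(dependent.variable.name = ".label", data = train,
                   num.trees = config$n_trees, mtry = mtry,
                   sample.fraction = config$sample_fraction, replace = TRUE,
                   probability = TRUE,
                   seed = derive_seed(config$seed, paste0("rf", seed_off)),
                   num.threads = 1)
  }
  if (config$mode == "oob") {
    fit <- fit_one(dat, 0)
    p <- fit$predictions[, "1"]
    if (anyNA(p)) {
      stop_domain(paste("some donors were never out-of-bag;",
                        "increase n_trees in forest_config()"))
    }
    unname(p)
  } else if (config$mode == "insample") {
    fit <- fit_one(dat, 0)
    unname(predict(fit, data = dat, num.threads = 1)$predictions[, "1"])
  } else {
    n <- nrow(dat)
    folds <- with_seed(derive_seed(config$seed, "folds"),
                       sample(rep_len(seq_len(config$k), n)))
    p <- numeric(n)
    for (f in seq_len(config$k)) {
      hold <- folds == f
      fit <- fit_one(dat[!hold, , drop = FALSE], f)
      p[hold] <- predict(fit, data = dat[hold, , drop = FALSE],
                         num.threads = 1)$predictions[, "1"]
    }
    p
  }
}
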