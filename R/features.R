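#' Build the donor-by-predictor feature table
#'
#' Pivots fitted kinetic parameters into one row per donor with columns
#' `fres_<subtype>` and `kdec_<subtype>` for each subtype (14 kinetic
#' candidates for the seven-subtype panel), optionally joined with
#' `age_at_draw`, plus the case/control `status` label. Donors missing any
#' fitted subtype are dropped and reported, so the table has no missing
#' values.
#'
#' @param params Parameter table from [fit_cohort()]`$params`.
#' @param donors Donor table (`donor_id`, `age_at_draw`, `status`).
#' @param include_age Add `age_at_draw` as a candidate predictor?
#' @return List with `table` (tibble: `donor_id`, features, `status`) and
#'   `dropped` (donor ids excluded for incomplete fits).
#' @export
build_feature_table <- function(params, donors, include_age = FALSE) {
  stopifnot(all(c("donor_id", "subtype", "kdec", "fres_scaled") %in% names(params)))
  wide <- tidyr::pivot_wider(
    dplyr::transmute(params, .data$donor_id,
                     subtype = sub("\\+$", "", .data$subtype),
                     fres = .data$fres_scaled, kdec = .data$kdec),
    id_cols = "donor_id", names_from = "subtype",
    values_from = c("fres", "kdec"), names_sep = "_")
  complete <- stats::complete.cases(wide)
  dropped <- wide$donor_id[!complete]
  wide <- wide[complete, , drop = FALSE]
  cols <- c("donor_id", if (include_age) "age_at_draw", "status")
  tab <- dplyr::inner_join(wide, donors[, cols], by = "donor_id")
  list(table = tibble::as_tibble(tab), dropped = dropped)
}

#' Augment a feature table with shadow features
#'
#' Duplicates every feature column as a "shadow": a permutation of its
#' values, independent of the class label by construction. Shadows are
#' re-drawn on every call; in the selection loop this happens once per
#' iteration.
#'
#' @param features Tibble/data frame of numeric feature columns only.
#' @param seed Optional integer seed for the permutations.
#' @return Tibble with the original columns plus `shadow_<name>` columns.
#' @export
make_shadow <- function(features, seed = NULL) {
  stopifnot(ncol(features) >= 1)
  # permutation stream keyed by feature name order, so column order is
  # irrelevant to the draws
  nm <- sort(names(features))
  draw <- function() {
    sh <- lapply(nm, function(v) sample(features[[v]]))
    names(sh) <- paste0("shadow_", nm)
    tibble::as_tibble(sh)
  }
  sh <- if (is.null(seed)) draw() else with_seed(seed, draw())
  dplyr::bind_cols(tibble::as_tibble(features)[nm], sh)
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' On each iteration the feature table is augmented with freshly permuted
#' shadow copies of every feature, a random forest is fit on features plus
#' shadows, and each real feature scores a "hit" when its permutation
#' importance exceeds the maximum importance among all shadows. After
#' `n_iter` iterations each feature's hit count is tested against the
#' fair-coin null with a two-sided exact binomial test, Bonferroni-corrected
#' over the real features: significantly above 1/2 is `confirmed`,
#' significantly below is `rejected`, otherwise `tentative`. Tentative
#' features are reported but not treated as selected downstream.
#'
#' @param features Numeric feature tibble (no label column, no missing
#'   values).
#' @param labels Binary 0/1 (or two-level) class labels, both classes
#'   present.
#' @param n_iter Number of shadow iterations (minimum 10).
#' @param alpha Family-wise significance level before Bonferroni correction.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param num_trees Trees per random forest.
#' @return A `selection_report`: list with `decisions` (tibble: `feature`,
#'   `hits`, `p_adj`, `decision`), `confirmed`, `n_iter`, `alpha`, `seed`.
#' @export
boruta_select <- function(features, labels, n_iter = 100, alpha = 0.05,
                          seed = 1L, num_trees = 200) {
  if (n_iter < 10) stop_domain("n_iter must be at least 10")
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop_domain("labels must contain exactly two classes")
  features <- tibble::as_tibble(features)[sort(names(features))]
  nm <- names(features)
  hits <- setNames(integer(length(nm)), nm)
  for (i in seq_len(n_iter)) {
    aug <- make_shadow(features, seed = derive_seed(seed, paste0("shadow", i)))
    dat <- data.frame(aug, .label = y, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = dat,
      num.trees = num_trees, importance = "permutation",
      seed = derive_seed(seed, paste0("forest", i)), num.threads = 1)
    imp <- fit$variable.importance
    imp[!is.finite(imp)] <- 0   # variables never used by any tree
    shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
    hits <- hits + as.integer(imp[nm] > shadow_max)
  }
  p <- vapply(hits, function(h)
    binom.test(h, n_iter, p = 0.5, alternative = "two.sided")$p.value, 0)
  p_adj <- pmin(1, p * length(nm))
  decision <- ifelse(p_adj < alpha & hits > n_iter / 2, "confirmed",
                     ifelse(p_adj < alpha & hits < n_iter / 2, "rejected",
                            "tentative"))
  report <- list(
    decisions = tibble::tibble(feature = nm, hits = unname(hits),
                               p_adj = unname(p_adj), decision = decision),
    confirmed = nm[decision == "confirmed"],
    n_iter = n_iter, alpha = alpha, seed = seed, num_trees = num_trees)
  class(report) <- "selection_report"
  report
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Shadow-feature selection: %d iterations, alpha = %g (Bonferroni)\n",
              x$n_iter, x$alpha))
  print(x$decisions, n = nrow(x$decisions))
  invisible(x)
}
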