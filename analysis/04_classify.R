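#!/usr/bin/env Rscript
# Stage 4: random-forest classification and inference.
#
# Fits three random-forest models with out-of-bag evaluation: the confirmed
# kinetic predictors alone, age at blood draw alone, and both combined.
# Reports AUC and accuracy with 95% percentile bootstrap CIs (10,000
# resamples), DeLong's test for the combined-vs-age AUC difference, and
# Fisher's exact test on the 2x2 correct/incorrect table.

suppressPackageStartupMessages(library(drcphenotype))

seed <- as.integer(Sys.getenv("DRC_SEED", "1"))
ft <- readr::read_csv("results/feature_table.csv", show_col_types = FALSE)
sel <- jsonlite::read_json("results/selection_report.json")
selected <- unlist(sel$confirmed)
if (length(selected) == 0) {
  message("No confirmed kinetic features; falling back to fres_CD19")
  selected <- "fres_CD19"
}
labels <- ft$status

fc <- forest_config(n_trees = 500, mode = "oob",
                    seed = derive_seed(seed, "classify"))
cmp <- compare_models(ft[c(selected, "age_at_draw")], ft["age_at_draw"],
                      labels, fc,
                      label_a = "selected_plus_age", label_b = "age_only")
scores_sel <- rf_fit_predict(ft[selected], labels, fc)

bseed <- derive_seed(seed, "bootstrap")
report_model <- function(scores, name) {
  ra <- roc_auc(scores, labels)
  auc_ci <- bootstrap_ci(scores, labels, "auc", 10000, 0.95,
                         derive_seed(bseed, paste0(name, "_auc")))
  acc_ci <- bootstrap_ci(scores, labels, "accuracy", 10000, 0.95,
                         derive_seed(bseed, paste0(name, "_acc")))
  message(sprintf("  %-18s AUC %.3f [%.3f-%.3f]  accuracy %.3f [%.3f-%.3f]",
                  name, ra$auc, auc_ci[["lo"]], auc_ci[["hi"]],
                  accuracy(scores, labels), acc_ci[["lo"]], acc_ci[["hi"]]))
  list(model = name, auc = ra$auc, auc_ci = as.list(auc_ci),
       accuracy = accuracy(scores, labels), accuracy_ci = as.list(acc_ci),
       n_bootstrap = 10000)
}

message("Out-of-bag performance (95% percentile bootstrap CIs):")
models <- list(selected = report_model(scores_sel, "selected_kinetics"),
               age = report_model(cmp$scores_b, "age_only"),
               combined = report_model(cmp$scores_a, "selected_plus_age"))

top <- selected[1]
assoc <- list(feature = top,
              spearman_r = spearman_cor(ft[[top]], labels),
              u_test = mann_whitney_u(ft[[top]][labels == 1],
                                      ft[[top]][labels == 0]))
message(sprintf("Association of %s with status: Spearman r=%.3f, U-test p=%.3g",
                top, assoc$spearman_r, assoc$u_test$p))
message(sprintf("Combined vs age: DeLong p=%.3g, Fisher p=%.3g",
                cmp$delong_p, cmp$fisher_p))

jsonlite::write_json(
  list(models = models, association = assoc, selected_features = selected,
       seed = seed),
  "results/classifier_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
jsonlite::write_json(
  cmp[c("model_a", "model_b", "auc_a", "auc_b", "delong_p",
        "acc_a", "acc_b", "fisher_p")],
  "results/comparison_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
readr::write_csv(roc_auc(scores_sel, labels)$roc, "results/roc_points.csv")
readr::write_csv(
  tibble::tibble(donor_id = ft$donor_id, status = labels,
                 prob_selected = scores_sel, prob_age = cmp$scores_b,
                 prob_combined = cmp$scores_a),
  "results/predicted_probabilities.csv")
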