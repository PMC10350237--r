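#!/usr/bin/env Rscript
# Stage 5: figures and run summary.
#
# Draws the ROC curves of the three models and a violin plot of the B-cell
# residual-damage parameter by case/control status, and writes a manifest
# of the run (seed, artifact checksums) for reproducibility.

suppressPackageStartupMessages({
  library(drcphenotype)
  library(dplyr)
})

seed <- as.integer(Sys.getenv("DRC_SEED", "1"))
ft <- readr::read_csv("results/feature_table.csv", show_col_types = FALSE)
probs <- readr::read_csv("results/predicted_probabilities.csv",
                         show_col_types = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  rocs <- bind_rows(lapply(
    c(selected = "prob_selected", age = "prob_age", combined = "prob_combined"),
    function(col) roc_auc(probs[[col]], probs$status)$roc),
    .id = "model")
  p1 <- ggplot(rocs, aes(fpr, tpr, colour = model)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_step(linewidth = 0.8) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = "ROC: selected kinetics vs age vs combined") +
    theme_minimal()
  ggsave("results/roc_curves.png", p1, width = 5.5, height = 5, dpi = 150)

  p2 <- ggplot(ft, aes(factor(status, labels = c("control", "case")),
                       fres_CD19)) +
    geom_violin(fill = "grey85") +
    geom_jitter(width = 0.08, alpha = 0.6, size = 1) +
    labs(x = NULL, y = "B-cell residual damage (Fres x D, signal units)",
         title = "CD19+ residual gamma-H2AX by case/control status") +
    theme_minimal()
  ggsave("results/fres_cd19_violin.png", p2, width = 4.5, height = 4.5,
         dpi = 150)
  message("Wrote results/roc_curves.png and results/fres_cd19_violin.png")
}

artifacts <- list.files("results", pattern = "\\.(csv|json)$",
                        full.names = TRUE)
manifest <- list(
  package_version = as.character(utils::packageVersion("drcphenotype")),
  seed = seed,
  checksums = as.list(setNames(unname(tools::md5sum(artifacts)),
                               basename(artifacts))))
jsonlite::write_json(manifest, "results/manifest.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("Wrote results/manifest.json")
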