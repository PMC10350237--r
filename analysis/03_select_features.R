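#!/usr/bin/env Rscript
# Stage 3: shadow-feature relevance filter.
#
# Builds the donor x predictor table (Fres and Kdec for each of the seven
# subtypes: 14 kinetic candidates) and runs the shadow-feature selector:
# 100 iterations, permutation importance against freshly permuted shadow
# copies, two-sided exact binomial test on hit counts with Bonferroni
# correction at alpha = 0.05. Age is held out of selection and only enters
# the combined classifier in stage 4.

suppressPackageStartupMessages(library(drcphenotype))

seed <- as.integer(Sys.getenv("DRC_SEED", "1"))
cohort <- read_cohort("results/cohort")
params <- readr::read_csv("results/repair_params.csv", show_col_types = FALSE)

ft <- build_feature_table(params, cohort$donors, include_age = TRUE)
readr::write_csv(ft$table, "results/feature_table.csv")
if (length(ft$dropped) > 0) {
  message("Dropped donors with incomplete fits: ",
          paste(ft$dropped, collapse = ", "))
}

kinetic <- setdiff(names(ft$table), c("donor_id", "age_at_draw", "status"))
sel <- boruta_select(ft$table[kinetic], ft$table$status,
                     n_iter = 100, alpha = 0.05, num_trees = 200,
                     seed = derive_seed(seed, "select"))
jsonlite::write_json(
  list(decisions = sel$decisions, confirmed = sel$confirmed,
       n_iter = sel$n_iter, alpha = sel$alpha, seed = sel$seed),
  "results/selection_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

print(sel)
message(sprintf("Confirmed predictors: %s",
                if (length(sel$confirmed)) paste(sel$confirmed, collapse = ", ")
                else "(none)"))
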