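#!/usr/bin/env Rscript
# Stage 2: fit the repair-kinetics model per donor and subtype.
#
# For each (donor, subtype) series: control-subtract the 3-Gy time course,
# pin the residual parameter (Fres x D) to the 20-hr normalized signal, and
# fit (Kprod, Kdec) by least squares on the natural-log scale over all five
# time points. Writes results/repair_params.csv.

suppressPackageStartupMessages({
  library(drcphenotype)
  library(dplyr)
})

cohort <- read_cohort("results/cohort")
fit <- fit_cohort(cohort$donors, cohort$signals, dose = 3)
readr::write_csv(fit$params, "results/repair_params.csv")
if (nrow(fit$skipped) > 0) {
  readr::write_csv(fit$skipped, "results/fit_skipped.csv")
}

message(sprintf("Fitted %d donor x subtype series (%d skipped)",
                nrow(fit$params), nrow(fit$skipped)))
summ <- fit$params |>
  group_by(subtype) |>
  summarise(kdec = median(kdec), fres = median(fres_scaled),
            sse = median(sse_log), .groups = "drop")
message("Median fitted parameters per subtype (fres = Fres x D):")
for (i in seq_len(nrow(summ))) {
  message(sprintf("  %-7s kdec=%.3f /hr  fres=%.2f  median log-SSE=%.3g",
                  summ$subtype[i], summ$kdec[i], summ$fres[i], summ$sse[i]))
}
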