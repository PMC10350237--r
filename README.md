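# drcphenotype

Phenotypic DNA repair capacity (DRC) profiling from gamma-H2AX repair
kinetics, with matched case-control classification.

## The problem

Decreased DNA repair capacity is a major cancer risk factor, but
genotype-based proxies capture little of the phenotype. A phenotypic DRC
assay challenges a donor's peripheral blood mononuclear cells (PBMCs) with
a fixed 3-Gy gamma-ray dose and follows the decay of gamma-H2AX — a
fluorescent marker of DNA double-strand breaks — at 1, 2, 3, 6 and 20 hours
after the challenge, separately in seven PBMC subtypes (CD3+, CD4+, CD8a+,
CD14+, CD19+, CD56+, TCRgd+). `drcphenotype` implements the downstream
analysis for epidemiologists and radiation biologists working with such
time courses:

1. **Kinetic modelling.** Per donor and subtype, after control
   subtraction, the signal is fit as
   `Y = Kprod·D·T·exp(−Kdec·T) + Fres·D·Ω` — production rate `Kprod`,
   repair rate `Kdec`, residual damage `Fres` (carried as the product
   `Fres·D`, pinned to the 20-hr signal; `(Kprod, Kdec)` by least squares
   on the natural-log scale over all five time points).
2. **Feature selection.** A shadow-feature (Boruta-style) filter over the
   14 kinetic candidates (`Fres`, `Kdec` × 7 subtypes): per-iteration
   random-forest importance against permuted shadow copies, exact binomial
   test on hit counts with Bonferroni correction.
3. **Classification & inference.** Random-forest case/control
   classification with out-of-bag probabilities; ROC/AUC, percentile
   bootstrap CIs (10,000 resamples), DeLong's test for paired AUCs,
   Fisher's exact accuracy comparison, Spearman correlation and the
   Mann-Whitney U test.
4. **Synthetic cohorts.** A seeded generator of age-matched case/control
   pairs with subtype-specific kinetics and a planted reduction of case
   B-cell (CD19+) residual damage, so the whole pipeline is testable
   without access to donor data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
46-pair cohort (`DRC_SEED` selects the seed; default 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_kinetics.R
Rscript analysis/03_select_features.R
Rscript analysis/04_classify.R
Rscript analysis/05_report.R
```

which prints, at seed 1:

```
Fitted 644 donor x subtype series (0 skipped)
...
Confirmed predictors: fres_CD19
Out-of-bag performance (95% percentile bootstrap CIs):
  selected_kinetics  AUC 0.839 [0.748-0.920]  accuracy 0.783 [0.696-0.859]
  age_only           AUC 0.394 [0.279-0.518]  accuracy 0.467 [0.370-0.565]
  selected_plus_age  AUC 0.829 [0.735-0.911]  accuracy 0.772 [0.685-0.859]
Association of fres_CD19 with status: Spearman r=-0.661, U-test p=2.8e-10
Combined vs age: DeLong p=2.2e-08, Fisher p=3.5e-05
```

Reading this: all 92 donors' series fit cleanly; of the 14 kinetic
candidates the shadow filter confirms exactly the planted one — residual
B-cell damage (`fres_CD19`), lower in cases — and an out-of-bag forest on
that single feature separates cases from controls with AUC 0.84. Age is
uninformative here by construction (pairs are age-matched and the
generator plants no age effect), so the combined model's advantage over
age alone is driven by the kinetic feature; in real case-control data age
itself is predictive and the combination is correspondingly stronger.

The same run is available as one call:

```r
library(drcphenotype)
res <- run_pipeline(pipeline_config(out_dir = "results/run1", seed = 1))
```

which writes `cohort_*.csv`, `repair_params.csv`, `feature_table.csv`,
`selection_report.json`, `classifier_report.json`,
`comparison_report.json`, `roc_points.csv` and a `manifest.json` with
seeds and artifact checksums; reruns with the same config are
byte-identical. To analyse measured data instead, point
`pipeline_config(cohort_dir = ...)` at a directory with
`cohort_donors.csv` (donor_id, pair_id, age_at_draw, status) and
`cohort_signals.csv` (donor_id, subtype, dose_gy, time_hr, signal).

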