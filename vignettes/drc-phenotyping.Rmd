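---
title: "Phenotypic DNA repair capacity: model, selection and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic DNA repair capacity: model, selection and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and the model

`drcphenotype` analyses a radiation-challenge assay of phenotypic DNA
repair capacity (DRC). Peripheral blood mononuclear cells (PBMCs) receive a
fixed 3-Gy gamma-ray challenge; the fluorescence of gamma-H2AX — a
phosphorylated histone marking DNA double-strand break sites — is then
measured at 1, 2, 3, 6 and 20 hours, separately in seven surface-marker
subtypes (CD3+, CD4+, CD8a+, CD14+, CD19+, CD56+ and TCRgd+, the last
denoting gamma-delta T cells). Unirradiated (0-Gy) tubes measured at 2 and
20 hours track the background.

The signal $Y$ at dose $D$ (Gy) and time $T$ (hr) is modelled per donor and
subtype as

$$Y = K_{prod}\, D\, T\, e^{-K_{dec} T} + F_{res}\, D\, \Omega,$$

with $\Omega = 1$ iff $D > 0$. $K_{prod}$ (signal/Gy/hr) is the initial
production rate of the damage signal, $K_{dec}$ (1/hr) the initial
exponential repair rate, and $F_{res}$ (signal/Gy) the residual
unrepaired/misrepaired signal after overnight incubation. Because the
challenge dose is fixed, the analysis carries the product $F_{res} D$
(`fres_scaled`) throughout; only its association with case status matters,
not its absolute units. The model implies a signal peak at $T = 1/K_{dec}$
and a long-time plateau at $F_{res} D$. Taken literally it also implies
$Y(0^+) = F_{res} D$ immediately after irradiation rather than 0; this
boundary behaviour is retained as-is, since no data lie near $T = 0$.

## Normalisation and fitting

Challenge measurements are control-subtracted before fitting: the 2-hr 0-Gy
value is subtracted from the 1, 2, 3 and 6-hr 3-Gy points, and the 20-hr
0-Gy value from the 20-hr 3-Gy point. The 1-hr point shares the 2-hr
control (no 1-hr sham tube exists in the design). Duplicate tubes at one
(dose, time) are rejected as errors rather than averaged: the design has
exactly one tube per design point.

`fres_scaled` is *pinned* to the observed normalised 20-hr signal, then
$(K_{prod}, K_{dec})$ minimise the sum of squared differences of natural
logs between the full model (residual term included) and the data over all
five time points. Numerical choices:

* **Clipping.** Log-scale least squares is undefined for non-positive
  values, and control subtraction can produce them; both model and data are
  clipped at $\varepsilon = 10^{-6}$ before logging and the clip count is
  recorded in the fit diagnostics. A series that is non-positive everywhere
  is a degenerate-fit error.
* **Negative residuals.** A negative pinned `fres_scaled` is retained as a
  legitimate data-driven feature value and flagged, not truncated.
* **Optimiser.** Deterministic bounded quasi-Newton (`L-BFGS-B` with
  analytic gradients, tight tolerances) from a fixed multi-start grid:
  seven $K_{dec}$ starts log-spaced over 0.05–2/hr, $K_{prod}$ matched to
  the 1-hr point at each start; best objective wins, ties to the smaller
  $K_{dec}$. This makes the fit a pure function of the data.
* **Validity domain of the pinning.** The pinned 20-hr value equals
  $F_{res} D$ plus the production-term remnant
  $K_{prod} D \cdot 20\, e^{-20 K_{dec}}$. For fast repair
  ($K_{dec} \gtrsim 0.8$/hr) the remnant is below $10^{-4}$ relative and
  parameter recovery on noiseless data is exact to that precision — the
  regime the package's exact-recovery and idempotence tests sample. At the
  default cohort baselines ($K_{dec}$ 0.3–0.45/hr) the remnant biases
  `fres_scaled` upward by up to ~6%; this cancels almost entirely in
  case/control contrasts and is irrelevant to classification, which uses
  the parameter only as a relative feature.

# The synthetic cohort generator

No per-donor dataset ships with the package, so a seeded generator emulates
the study conditions: 46 matched case/control pairs by default, ages from a
bounded normal (mean 55, sd 8, range 30–80 years) with the control's age
within ±2 years of its case. The kinetic triple for each subtype is drawn
**once per pair** — lognormal with log-sd 0.2 around the subtype baselines —
and shared by both pair members, the strongest form of matching; the case's
CD19+ $F_{res}$ is then multiplied by $1 - \text{case\_effect}$
(default 0.35, i.e. cases carry 35% less residual B-cell damage, the
direction associated with case status). Sharing parameters within pairs is
what makes the design's invariants exact: with noise off, non-CD19 signals
are identical within a pair, and the case:control ratio of the CD19+ 20-hr
signal equals $1 - \text{case\_effect}$ up to the production remnant.

Each measurement is the model mean times multiplicative lognormal noise
(log-sd 0.1 by default — fluorescence is positive and right-skewed) plus an
additive unirradiated background (0.5 signal units); 0-Gy rows therefore
measure the background alone, and noiseless normalisation recovers the
model mean exactly. One summary value is emitted per (donor, subtype, dose,
time): the single-cell layer (~1300 cell images per sample), gating and
fluorescence-spillover compensation of the real assay are **not**
simulated. Consequently, passing tests demonstrate that the pipeline
recovers structure of exactly this form; they say nothing about optical
artefacts, per-cell heterogeneity, or a real age–risk gradient (ages are
matched and carry no signal here, whereas age is a strong predictor in real
case-control data).

# Shadow-feature selection

The candidate predictors are `fres_scaled` and `kdec` for each of the seven
subtypes (14 kinetic candidates); age can be appended downstream but is
held out of selection. Each iteration augments the table with one freshly
permuted "shadow" copy per feature, fits a random forest on features plus
shadows, and scores a *hit* for every real feature whose importance exceeds
the maximum shadow importance. After `n_iter` iterations (default 100) each
hit count is tested against Binomial(n_iter, 1/2) with a two-sided exact
binomial test, Bonferroni-corrected over the real features at
$\alpha = 0.05$: significantly above — confirmed; below — rejected;
otherwise tentative. Design choices where the procedure is conventionally
underspecified:

* **Importance measure**: permutation importance on out-of-bag samples
  (the iteration count and importance type are configuration, not fixed by
  the method's definition).
* **Tentative features** are reported but treated as *not selected*
  downstream.
* **Order invariance**: features are processed in sorted-name order with a
  per-iteration seed stream, so decisions do not depend on column order.
* Importance of a variable never used by any tree is taken as 0.

# Classification and inference

Case probabilities come from a `ranger` random forest (500 trees by
default, sqrt-mtry, bootstrap resampling). The reported probabilities are
**out-of-bag** by default: each donor is predicted only by trees whose
bootstrap sample excluded it. This is the honest choice at n = 92 without
external validation — in-sample probabilities from a forest are nearly
separable by construction — and it materially lowers AUCs relative to
in-sample evaluation; `insample` and `kfold` modes are available in
`forest_config()`. Accuracy thresholds the probability at 0.5.

Inference toolkit:

* **ROC/AUC** — threshold sweep; the AUC equals all-pairs concordance with
  ties counting one half.
* **Bootstrap CIs** — percentile intervals over 10,000 resamples of donors
  with replacement (class-degenerate resamples are redrawn). Matched pairs
  exist in the design but their role in the original interval estimates is
  not recoverable, so donor-level resampling is the default and pair-level
  resampling is available via `pair_id`.
* **DeLong's test** — paired, two-sided, normal reference, with the
  structural-components covariance estimator; zero variance with equal
  AUCs returns p = 1.
* **Fisher's exact test** — the accuracy comparison uses the 2×2 table of
  models × (correct, incorrect) counts at threshold 0.5. A
  McNemar-style discordant-pair table would also be defensible; it is noted
  but not the default.
* **Spearman / Mann–Whitney U** — rank-based association and two-sample
  location tests for single features; the U test is exact (full
  enumeration) for combined n ≤ 12 without ties and tie-corrected normal
  otherwise.

The pipeline (`run_pipeline()` or the numbered `analysis/` scripts) derives
per-stage seeds from one global seed by stage name, so every artifact is a
pure function of (inputs, config, seed) and reruns are byte-identical; the
manifest records config, seeds and artifact checksums.

# Verification scale and limitations

The test suite verifies each component against independent oracles —
refined grid search for the kinetic fit; brute-force all-pairs concordance
for AUC; hypergeometric and permutation enumeration for the exact tests;
the reference structural-components implementation for DeLong; Monte-Carlo
calibration for type-I error (500 null repetitions, n = 200) and CI
coverage (500 cohorts of 92 donors, 1,000 bootstrap resamples each); and
multi-seed behavioural checks for selection (20 runs of 50 iterations) and
the end-to-end planted-effect pattern (20 cohorts of 46 pairs). These
problem sizes are the package's chosen verification scale: large enough for
the stated tolerances, small enough to run routinely.

Known limitations: single 3-Gy challenge only (no dose–response fitting);
one summary value per sample (no per-cell modelling); the pinning bias
discussed above for slow repair; and the synthetic age variable is
uninformative by construction, so combined-model gains over age here come
entirely from the kinetic feature.
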