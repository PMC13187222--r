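# scalenet

Network-based questionnaire item selection and ordinal psychometric
validation for two-group designs.

Developing a short self-report scale from a large item pool — for example,
reducing a 65-item trait questionnaire administered to a clinical and a
comparison group down to an 18-item instrument — involves a chain of
decisions that are usually scattered across several packages and ad hoc
scripts: which items are redundant, which discriminate between groups, how
many factors underlie the short form, whether the instrument measures the
same construct in both groups, and how well the final sum score separates
them. scalenet packages that chain as one reproducible workflow for
researchers in psychometrics and clinical/epidemiological measurement, and
ships a simulator that generates ordinal data with the same structure so
the entire pipeline is testable without any real dataset.

## What it computes

**Item selection.** Item-level pooled-SD Cohen's
*d* = (m₁ − m₂)/s_p assesses discrimination; a network connects item pairs
with *r* > 0.70, communities come from the walktrap algorithm (with a
deterministic modularity refinement), and four strategies — community
representatives, isolated discriminators, eigenvector-centrality hubs, top
discriminators — are unioned into the selected set with provenance tags.

**Exploratory factor analysis.** KMO and Bartlett factorability checks;
parallel analysis on principal-axis eigenvalues (reduced correlation
matrix, column-permutation reference); PAF extraction; direct oblimin
(quartimin) rotation by gradient projection; TLI/RMSEA from the ML
discrepancy; Thurstone factor scores with R² reliability.

**Ordinal CFA and invariance.** Polychoric correlations (two-step ML with
an in-package bivariate normal CDF), diagonally weighted least squares
estimation of the factor model (χ² unadjusted — not WLSMV-scaled, and
flagged as such), CFI/TLI/RMSEA/SRMR, McDonald's
ω = (Σλ)²/((Σλ)² + Σθ + 2Σcov), and a configural → metric → scalar
invariance sequence with ΔCFI ≤ 0.01 decisions (thresholds, the ordinal
analog of intercepts, are the scalar-level constraint).

**Discriminative validation.** ROC with midpoint thresholds, tie-corrected
Mann–Whitney AUC, the Youden-optimal operating point
(max sensitivity + specificity − 1), confusion-matrix metrics, Welch *t*,
and HC3-robust regression for covariate checks.

**Simulation.** A graded-response-style generator (normal latents,
per-item thresholds, reverse-keyed items, optional planted measurement
noninvariance) with a calibrator that hits a target observed-scale *d*
profile exactly under the threshold model, plus named study-shaped
fixtures (`sample1_like`, `two_factor_invariant`, `metric_violation`, ...).

## Worked example

```r
library(scalenet)

fx <- make_fixture("sample1_like", seed = 9)   # 196 + 196, 65 items
report <- run_pipeline(list(
  input = fx$matrix,
  stages = c("item_selection", "efa", "validity"),
  reverse_items = fx$ground_truth$reverse_items,
  seed = 5))

length(report$stages$item_selection$selected)
#> [1] 17
report$stages$efa$n_factors
#> [1] 2
round(report$stages$validity$cohens_d, 2)
#> [1] 3.45
round(report$stages$validity$auc, 3)
#> [1] 0.991
round(report$stages$validity$alpha, 3)
#> [1] 0.97
```

Read: from 65 synthetic items the multi-strategy selection kept 17; the
selected set is two-dimensional by parallel analysis; its sum score
separates the groups at *d* ≈ 3.5 with AUC ≈ 0.99 and internal consistency
α ≈ 0.97 — the behaviour expected when the planted discrimination profile
spans *d* = 0.8–2.44.

The confirmatory side works the same way:

```r
spec <- cfa_spec(list(F1 = paste0("IP", 1:12), F2 = paste0("IP", 13:18)))
fi <- make_fixture("two_factor_invariant", seed = 21)
print(invariance_sequence(fi$matrix, spec))
#> Measurement invariance (comparison n = 500, case n = 500)
#>   configural chisq(268) =   168.05, CFI = 1.000, RMSEA = 0.000  [pass]
#>   metric     chisq(284) =   239.91, CFI = 1.000, ... dCFI = -0.0000  [pass]
#>   scalar     chisq(390) =   347.29, CFI = 1.000, ... dCFI = -0.0000  [pass]
```

A group difference planted purely in the latent means passes all three
levels; planted loading violations inflate the metric step.

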