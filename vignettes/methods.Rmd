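---
title: "Methods: network-based item selection and ordinal validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based item selection and ordinal validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

scalenet implements a five-stage workflow for turning a large pool of
ordinal questionnaire items into a short, validated scale in a two-group
(case vs comparison) design, together with a simulator that generates data
with the same structure so that every stage can be exercised and checked
end-to-end. This vignette explains the models behind each stage, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic data can and cannot tell you about behaviour on real data.

## The data model

All stages consume a `response_matrix`: participants × items integer
ratings on a 1..K scale (K = 7 by default) plus a binary group label.
Reverse-keyed items are recoded as `K + 1 − x` before any correlation or
discrimination statistic is computed, so that a higher keyed rating always
means more of the latent trait. Total scores are plain sums over an item
subset with the same reverse-coding rule.

## Stage 1: network-based item selection

Item-level discrimination is the pooled-SD Cohen's d between groups.
The item network connects every pair of items whose correlation strictly
exceeds a threshold (default 0.70); Pearson correlations on the raw
(keyed) ratings are the default, with Spearman and polychoric available —
the choice matters little at 7 categories but polychoric is the coherent
companion to the ordinal factor models below. Items below the threshold are
not discarded: they stay on a separate isolated-candidates list.

Communities among the networked items come from the walktrap algorithm
(short random walks define node distances, communities are merged
agglomeratively, and the best cut of the merge path by weighted modularity
is returned; walk length defaults to the canonical 4). Because the
merge-path cut can be noticeably sub-optimal on small graphs with
near-uniform weights, the returned partition is additionally polished by a
deterministic greedy refinement (single-node moves and whole-community
merges until no move increases modularity, also compared against a
singletons start). On graphs small enough to enumerate, this brings the
partition within 0.05 of the exhaustive modularity optimum in all our
property tests.

Degree is the raw count of incident edges; eigenvector centrality is the
leading eigenvector of the weighted adjacency, computed per connected
component and max-normalised to 1 within each component (a global
normalisation would zero out smaller components).

Selection combines four strategies: (1) the highest-d member of every
community with at least `min_community_size` members (default 2); (2) the
`k_isolated` (5) isolated items with highest d; (3) the `k_hubs` (8)
networked items with highest eigenvector centrality; (4) the `k_top` (12)
items with highest d overall. The result is the deduplicated union with
per-item provenance tags. Ties break by higher d, then lexicographic item
id, with ranking keys rounded to 9 decimals so that numerically identical
centralities tie exactly — this makes the selection invariant to item
order. The cardinality defaults were chosen so that the default synthetic
fixture yields a selection in the high-teens (17–21 items across seeds),
the scale size this workflow is designed to produce; they are configuration
parameters, not estimates of how any published instrument was actually
derived.

## Stage 2: exploratory factor analysis

Factorability is checked with the Kaiser–Meyer–Olkin index (squared
correlations against squared anti-image partial correlations; defined as 0
for a diagonal matrix where both sums vanish) and Bartlett's sphericity
test, `χ² = −(n − 1 − (2p + 5)/6)·log det R`.

The number of factors comes from parallel analysis on principal-axis
eigenvalues: observed eigenvalues of the reduced correlation matrix
(squared multiple correlations on the diagonal) are compared with the 95th
percentile of the same eigenvalues from column-permuted data (1000
resamples by default; permutation preserves the ordinal marginals while
destroying the correlations). The retained number is the leading run of
observed > reference positions.

Extraction is classic principal axis factoring: iterate the
eigendecomposition of the reduced correlation matrix, replacing the
diagonal with the implied communalities, until `max |Δh²| < 1e−6` (at most
1000 iterations). Communalities above 1 (Heywood cases) are clipped at 1
with a warning. Multi-factor solutions are rotated by direct oblimin
(γ = 0, i.e. quartimin) via the gradient projection algorithm, with 10
random orthonormal starts in addition to the identity and a gradient-norm
stopping rule of 1e−6 (tighter than the 1e−5 used by the common
implementations); `Λ Φ Λᵀ` is preserved exactly by construction of the
oblique rotation. Factor columns are ordered by explained variance with
non-negative column sums, making the output deterministic.

Fit indices for the EFA are computed from the maximum-likelihood
discrepancy of the (PAF) solution to the sample correlation matrix:
`χ² = (n − 1)·F`, `df = ((p − m)² − (p + m))/2`, with the independence
model as baseline; RMSEA's 90% interval inverts the noncentral χ². Because
the discrepancy is evaluated at the PAF rather than the ML solution, the
χ² is conservative (slightly too large); the indices are meant for the
relative comparisons the workflow needs, not as a reimplementation of any
particular EFA program's internals.

Factor scores are Thurstone regression scores, `W = R⁻¹ Λ Φ`; score
reliability is the squared multiple correlation of each factor on the
items, `R²_j = (ΛΦ)ⱼᵀ R⁻¹ (ΛΦ)ⱼ`, reported with its square root as the
correlation-with-factor.

## Stages 2 & 4: ordinal CFA and measurement invariance

Ordinal items are modelled as discretisations of normal latent responses.
Polychoric correlations are estimated in two steps — thresholds from the
marginal category proportions via the normal quantile, then ρ by maximising
the bivariate-normal likelihood of the contingency table. The bivariate
normal CDF is computed in-package by 48-node Gauss–Legendre quadrature of
the single-integral reduction (absolute accuracy around 1e−6 even at
|ρ| = 0.95, far below the statistical noise of any realistic sample); the
ρ search uses golden-section/parabolic optimisation on (−0.999, 0.999) and
clips boundary drift to ±0.999 with a warning.

The CFA is estimated by diagonally weighted least squares on the
polychoric correlations: minimise `Σⱼ (sⱼ − σⱼ(θ))² / wⱼ` over the
lower-triangle correlations, where `wⱼ` is the finite-sample variance of
the j-th polychoric estimate obtained from the observed information of its
pairwise likelihood (thresholds held fixed). The reported test statistic is
the minimised discrepancy itself — numerically the same as scaling an
n-free weight matrix by n − 1 — and is *not* mean-and-variance adjusted:
full WLSMV scaling is deliberately out of scope, every fitted object
carries that flag, and the raw χ² should be read as a discrepancy measure
feeding CFI/TLI/RMSEA/SRMR rather than as a calibrated p-value source.
Identification fixes factor variances to 1 with all loadings free
(standardized solution); residual variances are `1 − communality`; error
covariances enter only as explicitly specified model options (no
modification-index search). The optimizer is `nlminb` with box constraints
(|λ| ≤ 0.995), data-driven starts, three jittered restarts, and a
gradient check on non-convergence. McDonald's ω per factor is
`(Σλ)² / ((Σλ)² + Σθ + 2Σ error-covariances)`.

Measurement invariance fits the two-group model at three nested levels.
The moment vector per group stacks all K−1 thresholds per item (full
category grid, with boundary proportions clamped into
`[1/(2n), 1 − 1/(2n)]` so empty extreme categories stay finite) and the
polychoric correlations; threshold moments are weighted by their
delta-method precisions.

* **Configural**: same pattern, all parameters free per group; thresholds
  saturated. Equivalent to independent per-group fits.
* **Metric**: loadings constrained equal; the case group's factor
  variances and covariances are freed (the standard compensation);
  thresholds still saturated.
* **Scalar**: loadings and thresholds constrained equal, case-group latent
  factor means freed. Constraining thresholds is the ordinal analog of
  intercept invariance — that is what "scalar" means here, stated
  explicitly because with ordinal indicators both intercept- and
  threshold-based definitions are defensible.

Estimation at the scalar level is two-stage: the correlation structure is
the metric-level fit (threshold constraints cannot change implied
correlations, which are scale-free), and the threshold discrepancy is then
minimised over the common thresholds — profiled out in closed form per
item — and the case-group factor means. This makes the scalar statistic a
(tight) upper bound on the fully joint minimum, keeps χ² weakly increasing
and df strictly increasing across levels by construction, and runs in
seconds. The reference group (variance 1, mean 0) is the comparison group.

Decisions use the conventional ΔCFI rule: a level passes if the CFI drop
from the previous level is at most 0.01 (configural itself passes if
CFI ≥ 0.95); the ΔRMSEA change is reported against 0.015 alongside χ²
difference tests, but CFI is the primary rule. The baseline model (zero
correlations, saturated thresholds) is shared across levels; because its
df can be smaller than the scalar model's df, CFI is computed with the
max-form denominators, which remain well defined in that regime.

A power caveat worth knowing: with 18 items, n = 500 per group, and a
loading violation of −0.3 on four items, the population ΔCFI at the metric
step is ≈ 0.012 — just above the 0.01 rule — so single-sample decisions
near the boundary are noisy (the Δχ² test, by contrast, detects this
violation essentially always). Users who need high per-sample power for
violations of this size should rely on Δχ² or larger samples.

## Stages 3 & 5: discriminative validation

The ROC threshold grid is the set of midpoints between adjacent distinct
observed scores plus sentinels; classification predicts "case" iff
score > t (direction auto-detected from group means and overridable). This
midpoint convention is why integer sum scores yield half-integer optimal
cutoffs. AUC is the tie-corrected Mann–Whitney statistic (ties credited
1/2), identical to the trapezoidal area under the empirical curve. The
operating point maximises Youden's J = sensitivity + specificity − 1; ties
break toward the more balanced sensitivity/specificity pair, then the
lower threshold. Sensitivity, specificity and accuracy follow the usual
confusion-matrix definitions. Group comparisons on total scores use
Welch's t and pooled-SD Cohen's d; the gender/covariate regressions the
workflow supports use OLS with HC3 sandwich standard errors.

## The synthetic-data generator

`generate_responses()` draws from a graded-response-style model: factors
`f ~ N(μ_g, Φ)`-equivalent structure (implemented as a per-item latent
offset for the case group), latent response
`y* = λᵢᵀ f + shiftᵢ·[case] + ε`, `ε ~ N(0, 1 − communality)`, discretised
by per-item strictly increasing thresholds; reverse-keyed items are
emitted as `K + 1 − x`. Defaults: 65 items, two factors with loadings 0.7
in blocks, factor correlation 0.58, thresholds equally spaced and
symmetric (±0.5, ±1.5, ±2.5) — a neutral, configurable choice, since the
emulated study does not report item thresholds or variances; these
defaults are free parameters of the simulator, not estimates of any real
instrument's items. Reverse-keyed defaults are items 6, 13, 21 and 55.

`induce_d_profile()` calibrates per-item case-group offsets so the
model-implied *observed-scale* d (computed exactly from the category
probabilities of the threshold model, equal-n pooling) hits a target
profile to within 1e−3, diagnosing items whose thresholds saturate before
the target is reachable. The named fixtures encode the study-shaped
conditions: `sample1_like`/`sample3_like` (196+196 / 30+30 participants,
65 items, d profile spanning 0.80–2.44 interleaved across both factor
blocks), `two_factor_invariant` (18 items = 12 + 6, loadings 0.7,
Φ = 0.58, a pure latent factor-mean shift of 1.5 per factor —
scalar-invariant by construction since the per-item offsets are `Λα`),
`metric_violation` (the same with four case-group loadings, two per
factor, lowered by 0.3) and `null_model` (no group effect).

What the simulator does *not* emulate: item nonresponse, acquiescence or
straightline response styles, cross-loadings, skewed threshold
configurations, or correlated residuals beyond those explicitly requested.
Passing tests on this generator therefore show that the estimators recover
the graded-threshold factor family they assume; they do not certify
behaviour under the response artefacts real questionnaire data can carry.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; fixed seed means
bit-identical output (the pipeline derives per-stage substreams from one
root seed). The test-suite Monte-Carlos use problem sizes chosen to give
stable rates at interactive runtimes: 100 seeds for the parallel-analysis
retention rate, 50 seeds for each invariance-decision rate, 150–200
permutation resamples inside test-time parallel analyses (the package
default stays at 1000), and parameter-recovery checks that assess
per-parameter bias across replications (at these sample sizes the max
elementwise error of even a perfect estimator straddles ±0.05 by sampling
noise alone, so bias is the meaningful recovery metric).

## Known limitations

* The DWLS χ² is unadjusted; its absolute calibration is poor (that is
  precisely what WLSMV scaling exists for), so fit indices should be used
  comparatively.
* The scalar-level fit is a two-stage profile, an upper bound on the joint
  minimum; in all synthetic checks the gap is negligible, but it is not
  the exact joint optimum.
* The EFA χ² uses the ML discrepancy of the PAF solution (conservative).
* Polychoric estimation is pairwise two-step; no underlying-normality test
  is performed.
* ΔCFI-based invariance decisions have limited power near the 0.01
  boundary (see the power caveat above).
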