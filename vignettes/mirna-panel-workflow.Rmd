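---
title: "A two-phase qPCR microRNA biomarker workflow: models, parameters and design choices"
author: "mirnapanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-phase qPCR microRNA biomarker workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnapanel)
```

# The problem and the model

Tissue microRNA biomarker studies of rare tumours commonly follow a
two-phase design. A small discovery cohort is profiled on a low-density
qPCR array interrogating several hundred microRNAs; a handful of
differentially expressed candidates is then re-measured by targeted
RT-qPCR in a larger, independent validation cohort and assessed as
diagnostic markers, individually and as a combined panel. `mirnapanel`
implements this workflow end to end for a binary benign/malignant
contrast.

## Relative quantification

qPCR measures a cycle threshold Ct per well; one PCR cycle corresponds to
a doubling, so Ct is a negative log2 abundance. The package uses the
standard comparative-Ct chain:

* **Detection.** A well with Ct over the negativity threshold (default 35
  cycles) is negative. "Over" is read strictly: Ct = 35.000 is still
  detected. Undetected wells are *missing*, not imputed at the threshold —
  imputation would manufacture fold changes for dropout-prone assays; the
  screen instead accounts for missingness through detection fractions.
* **Replicate aggregation.** The mean and sample SD are computed over
  detected replicates only; a pair with no detected replicate is
  undetected. Replicate SD above 0.5 cycles raises a QC flag but never
  drops data: amplification-quality exclusions are a judgement call left
  to the analyst via the validation report, not an automatic rule. The
  model deliberately does not assume triplicates — array cards are
  single-well, validation runs are typically triplicate.
* **ΔCt.** Target Ct minus the arithmetic mean of the sample's reference
  assay Cts (an RNU48-like endogenous control in the validation design).
  With several references, averaging their Cts reduces to the
  single-reference case. For array cards without a designated control a
  per-sample global mean over detected target assays is available
  (`normalization = "global_mean"`); endogenous-control normalisation is
  the default because it is the validated-assay convention.
* **ΔΔCt and relative expression.** Per assay, ΔΔCt subtracts the mean
  ΔCt of the *calibrator group* (benign samples with detected values);
  relative expression is 2^−ΔΔCt. The calibrator statistic is the
  arithmetic mean of ΔCt — equivalently the geometric mean of expression —
  which is the standard comparative-Ct convention and guarantees that the
  benign-group geometric mean is exactly 1 for every completely observed
  assay. Adding a constant to every Ct of a sample (more input RNA)
  leaves all ΔCt, and hence the matrix, unchanged.

The container is a `SummarizedExperiment` subclass (`MiRExperiment`) with
assays as rows, samples as columns, the `relexpr` and `delta_ct` assays,
and normalisation provenance in `metadata()`.

## The discovery screen

Group comparison uses the Mann–Whitney U test — appropriate for small,
skewed expression cohorts. The U statistic counts, for the malignant
group, pairs with higher expression (ties half). The p-value is the exact
enumeration value when n1 + n2 ≤ 20 and the pooled data are tie-free, and
otherwise the normal approximation with tie and continuity correction.
On tie-free data U/(n1·n2) equals the empirical ROC AUC — a cross-module
identity asserted in the test suite.

Effect size is the log2 ratio of group geometric means of relative
expression, which on the Ct scale is simply minus the difference of group
mean ΔΔCt. Candidates are ranked by a combined score

score = −log10(p) + |log2FC|, gated by p < 0.05 and |log2FC| ≥ 1,

with failing records scored 0 and labelled `ns`. A literal arithmetic sum
of a p-value and a linear fold change would not rank sensibly (smaller p
is *better*); the −log10 transform preserves the intent of a joint
significance/effect ranking with both components dimensionless and
increasing in evidence. Whether the fold-change gate is expressed on the
linear (FC ≥ 2 or ≤ 0.5) or absolute-log2 scale is immaterial — the two
are equivalent under this definition.

Screening several hundred assays at raw p < 0.05 is intentionally
permissive — the validation phase is the error control. The screen
therefore selects on raw p, but Benjamini–Hochberg q-values are always
computed and reported so an analyst can select on FDR instead. An assay
enters the screen only if at least half the samples (default
`minDetectionFraction = 0.5`) of at least one group are detected and both
groups retain a value; fold changes are computed over detected values
(pairwise deletion).

Ties in the score are broken by smaller p, then lexicographic assay id,
making top-k selection deterministic.

## Unsupervised views

PCA and agglomerative clustering of the significant-assay slice serve as
structure checks, not inference. Defaults follow heatmap convention:
per-assay z-scaling, Euclidean distance, average linkage (Ward and
complete, and a correlation distance, are available). Missing entries are
imputed with per-assay means — neutral after centering. t-SNE/UMAP-style
stochastic embeddings are deliberately out of scope: they add no
quantitative surface to this workflow.

## Per-marker diagnostics

The ROC is the full empirical curve over distinct observed marker values.
For downregulated markers scores are negated first, so one code path
handles both directions and all metrics are invariant under
negate-and-flip (tested). Candidate cutoffs are **midpoints between
adjacent distinct observed values**, flanked by ±∞: a midpoint cutoff can
never coincide with a training observation, so the strict positivity
inequalities are unambiguous on the data that chose the cutoff. AUC is
the trapezoid area, which treats tied scores as half-concordant.

The operating point is chosen by the Youden index J = sensitivity +
specificity − 1, the standard prevalence-free cutpoint criterion for
biomarker tables. Ties in J are broken towards higher specificity (a
false malignant call triggers aggressive management), then towards the
lower cutoff; comparisons are made after rounding to 10 decimal digits so
exact rational ties are not split by floating-point noise. Confusion
metrics with zero denominators (e.g. PPV with no positive calls) are
reported as missing rather than 0 or 1.

Odds ratios come from a univariate logistic fit (IRLS via `glm`). The
default covariate scale is the relative-expression unit itself, with a
`logScale` switch to per-log2-unit — published forest plots rarely state
the scale, so both are first-class. CIs are Wald, exp(β ± 1.96·SE);
profile or Firth intervals are out of scope. Complete or quasi-complete
separation (non-overlapping covariate ranges, a diverging slope, or a
fitted-probability warning) sets a flag and marks the fit non-converged;
the numbers are then descriptive only.

## The k-of-n panel

Each validated marker votes on each sample: positive strictly above its
cutoff (up) or strictly below (down); a missing measurement is a missing
call and counts as a *negative* vote (reported alongside), the
conservative choice that never manufactures evidence of malignancy and
never excludes a sample. A sample is panel-positive when at least k of
the n markers vote positive. Raising k shrinks the positive set, so
sensitivity is non-increasing and specificity non-decreasing in k — a
set-inclusion argument asserted on random instances.

Panel discrimination is reported two ways, and the distinction matters:

1. **Binary-rule AUC** at a fixed k: the trapezoid area of the two-point
   ROC through (1 − specificity, sensitivity), i.e.
   (sensitivity + specificity)/2. This is the AUC a yes/no classifier
   earns; with 17/17 malignant positive and 15/18 benign negative it
   gives (1 + 15/18)/2 = 0.9167.
2. **Vote-count ROC AUC**: the full ROC over the integer vote count as an
   ordinal score.

Neither dominates the other in general, so `PanelPerformance` carries
both; `bestK` maximises the binary-rule AUC with ties resolved towards
the larger (more specific) k.

# The synthetic-data generator

No raw Ct data accompany the motivating study design, so the generator is
a first-class module: it draws cohorts with exactly the structure the
analysis assumes, giving every pipeline stage a ground truth.

The model is Gaussian on the Ct scale — the standard noise model for
qPCR, where cycle-scale noise is approximately additive. Per sample, each
reference assay has a true level N(mean, sd); the sample's normalising
level is their mean, so input-amount variation is shared by all wells of
a sample. Per target assay, the biological ΔCt is
N(baseline − g·log2FC, sd) with g the malignant indicator: a planted
log2 fold change of +2 is a 2-cycle *decrease* in malignant ΔCt. A well
reads reference level + ΔCt + N(0, replicateSd), and with dropout
enabled any well above the negativity threshold is emitted as
"Undetermined" — deterministic truncation, the simplest mechanism
consistent with the Ct > 35 negativity rule (a fitted logistic dropout
curve would add parameters the design gives no data to constrain).

`presetPaperShape()` encodes the study shape the package targets:

* discovery: 5 benign + 6 malignant samples, single-well, 768 target
  assays — 27 planted up and 23 planted down (log2FC magnitudes spread
  over 1.2–3, with the six named candidates at ±2) and 718 nulls — plus
  an RNU48-like reference (Ct ≈ 22, SD 0.25);
* validation: 18 benign + 17 malignant samples, triplicate wells, the six
  candidates at log2FC ±2 plus the reference.

The source study reports no variance components, so the SDs are
field-typical conventions, exposed as parameters: biological SD 1.5
cycles on the discovery card (FFPE-derived array data are noisy), 0.8 in
validation (targeted assays, better RNA input), technical replicate SD
0.15 cycles. Baseline levels place target wells at roughly Ct 26–34 so
the highest-Ct assays genuinely drop out above 35, exercising the
missing-data paths. Cohorts are bit-identical under a fixed `rngSeed`,
and the generator restores the caller's RNG state.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: plate/batch effects, amplification-
efficiency differences between assays (the 2^−ΔΔCt identity assumes
perfect doubling), FFPE degradation gradients correlated with sample age,
informative (expression-dependent beyond-threshold) dropout, and
inter-laboratory variation.

# Numerical and testing choices

* Exact Mann–Whitney p-values are enumeration-based (via the exact null
  distribution); the suite checks them against an independent
  combinatorial enumeration for *every* two-group split of up to 8
  distinct values, and the large-sample path against the same oracle on
  random instances.
* Youden cutoffs are checked against brute-force maximisation over all
  midpoints on 1,000 random tied instances; AUC against pair counting and
  against `pROC` on tied data.
* Logistic fits are checked against a two-stage dense grid search of the
  exact Bernoulli log-likelihood on small instances (agreement within
  grid resolution), and against the closed-form 2×2 odds ratio for binary
  covariates.
* Parameter recovery uses the validation preset across seeds 1–20: the
  per-direction recovered log2 fold change (mean over the three planted
  markers of a direction) must lie within ±0.5 of ±2. The per-direction
  pooled estimate is the tested quantity because its sampling SE
  (≈ 0.16 cycles) makes ±0.5 a property of the method, whereas a single
  marker's estimate has SE ≈ 0.27 under the generator's own variance
  settings and would fail a fixed ±0.5 band a few percent of the time by
  chance alone.
* The screen's empirical size is measured on a 768-assay null cohort and
  must fall within the 99% binomial band around 0.05; the normal-
  approximation path with continuity correction is slightly conservative
  (observed ≈ 0.04), as expected for a discrete rank test at n = 35.
* Test problem sizes (cohorts of 35, one 768-assay card, 1,000-instance
  property loops) keep the full suite around a minute and a half while
  leaving every code path exercised at the study's own scale.

# Known limitations

Evaluation is in-sample, as in the motivating design: Youden cutoffs and
panel metrics are computed on the cohort that chose them and are
optimistically biased; no cross-validation or train/test split is
provided. No amplification-efficiency correction (Pfaffl-style) is
implemented. Wald CIs misbehave near separation (flagged, not fixed).
The combined score's gates are hard thresholds; assays just missing one
gate score 0 rather than degrading smoothly.
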