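---
title: "Radiogenomic staging of bladder cancer: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiogenomic staging of bladder cancer: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clinical staging of muscle-invasive bladder cancer separates tumors still
confined to the bladder (intra-vesical) from tumors that have grown through
the muscle into perivesical fat (extra-vesical). The distinction drives the
choice between bladder-preserving treatment and radical cystectomy, yet
axial imaging mis-stages roughly a third of patients in each direction.
`rgstage` implements a radiogenomic staging pipeline: quantitative texture
and shape features from T2-weighted MR tumor volumes are combined with
RNA-seq-derived predictors (differential expression and per-sample gene-set
enrichment), screened, and fed to small supervised classifiers whose
predictor budget is deliberately capped.

Real patient data of this kind is not publicly distributable, so the
package pairs every analysis stage with a seeded synthetic cohort generator
that plants known effects. All statistical behavior documented here is
measured on those synthetic cohorts; the tests quantify whether each method
recovers what was planted, at what error rate — they say nothing about
staging accuracy on real MR scans.

# Radiomic engine

Features are computed strictly inside a binary tumor mask after min-max
scaling of the whole volume to [0, 1]. Masked intensities are discretized
to `N = 2^x` gray levels over the masked min–max range
(`level = min(N, floor(N (v - min)/(max - min)) + 1)`), so every
discretized-texture feature is invariant to increasing affine transforms of
the raw intensities. Three sweep parameters mirror a standard radiomics
protocol:

* **bin exponent** `x` in 1..8 — gray-level counts 2, 4, ..., 256;
* **kernel size** 1..5 — one parameter with per-family semantics: the
  pair offset distance for the co-occurrence matrix, and the Chebyshev
  neighborhood radius for the dependence and gray-tone-difference
  families;
* **angle** in {0°, 45°, 90°, 135°} — in-plane directions applied per
  axial slice; opposite directions are redundant because co-occurrence
  matrices are symmetrized.

Seven families are emitted: 15 first-order statistics, 20 co-occurrence
(GLCM), 15 run-length (GLRLM), 14 size-zone (GLSZM, 26-connected zones),
12 dependence (GLDM), 5 neighborhood gray-tone difference (NGTDM) and 20
shape features. The run-length list drops `LongRunHighGrayLevelEmphasis`
and the size-zone list drops the two remaining cross terms relative to the
16-member consensus sets; the trims are frozen catalog constants (the family sizes above are the
package's fixed contract). A full sweep emits
`20 + 15·8 + 20·8·5·4 + 15·8·4 + 14·8 + 12·8·5 + 5·8·5 = 4612` records per
case; a single parameter triple emits 101.

Numerical conventions, stated once and used everywhere: population
(n-denominator) variance, skewness and kurtosis; kurtosis is non-excess
(3 for a Gaussian); percentiles use linear interpolation; first-order
`Entropy`/`Uniformity` use the discretized histogram. Any feature whose
value would be non-finite (zero variance for GLCM `Correlation`, a
single-level ROI for NGTDM `Busyness`, planar masks for the least-axis
shape features) is flagged `operable = FALSE` and carries `NA`, never a
raw `NaN`/`Inf`.

## Surface area

Two estimators are provided because they answer different questions.
Voxel-face counting (the default) measures the voxelized solid exactly —
a cube of side `a` gives exactly `6a²` and sphericity `(π/6)^{1/3} ≈
0.806` — but overestimates the area of the smooth surface underlying a
digitized shape by up to ~50% (staircase effect). The `"smoothed"`
estimator integrates the gradient magnitude of a Gaussian-smoothed
indicator (`σ = 0.6` voxels, co-area formula) and tracks the underlying
smooth surface instead: digitized balls with radii 6–10.5 voxels give
sphericity 0.991–1.000 (calibrated once; the test asserts [0.9, 1.0]).
`MeshVolume` equals `VoxelVolume` by construction (the volume enclosed by
the voxel boundary), and downstream redundancy reduction removes the
duplicate.

# Genomic pipeline

Counts are normalized with median-of-ratios size factors. Differential
expression is a deliberately transparent negative-binomial Wald test: the
per-gene dispersion is the method-of-moments estimate
`α = max(0, (var - mean)/mean²)` from pooled within-group moments of
normalized counts, the log2 fold change contrasts extra- over
intra-vesical group means, and the standard error follows from
`Var(K/s) = μ + αμ²` by the delta method. Two-sided p-values use a t
reference with `n₁ + n₂ − 2` degrees of freedom rather than the normal: at
n = 10 + 10 the moment dispersion estimate is noisy (and clamped at zero),
and the normal reference was measurably anticonservative in the far tail —
enough to push the observed false discovery proportion of a BH-0.05 screen
to ~0.18; the t reference restores both uniform null p-values and
FDR ≤ 0.05 in the planted-effect simulations. There is no dispersion
shrinkage, outlier replacement or independent filtering: with tens of
samples per group and planted effects of 1–2 log2 units, shrinkage is not
the binding constraint, and the moment estimator keeps every number in the
pipeline derivable by hand. The trade-off is honest: at 2–5 samples per
group the unshrunken test is noticeably less powerful than an
empirical-Bayes analysis, and the test suite only claims calibration
(uniform null p-values, BH-FDR control) and recovery at the planted study
conditions (log2FC = 2, n = 10 + 10, ≥ 90% recovery at FDR ≤ 0.1).

Per-sample gene-set activity uses the single-sample enrichment score: genes
are ranked by expression within each sample (average ranks on ties;
descending), and a set's score is the summed difference between the
rank-weighted in-set running distribution (weight `r^α` with `α = 0.25`,
where `r` is largest for the most highly expressed gene — the reading that
up-weights top genes, as the canonical algorithm does) and the uniform
out-of-set running distribution. Scores are rank-based, hence invariant to
any monotone per-sample transform; the expression input is
size-factor-normalized `log1p` counts purely for interpretability of the
matrix itself. Stage trends across ≥ 2 groups use Kruskal–Wallis tests
with significance stars bucketed at 0.05/0.01/0.001/0.0001.

# Radiomic feature screening

Cleaning removes features that are inoperable for any case and
zero-variance features. (Screening-stage descriptions in this field sometimes speak of
eliminating "nonzero" values; read literally that would discard all
data, so this package eliminates non-finite/inoperable values and says
so here prominently.) Redundancy reduction is greedy
correlation pruning — features ordered by screening p-value, a candidate
dropped when `|r| > 0.95` against any retained feature; the method and its
threshold are package choices (a config knob); only the goal — reduce
redundancy before screening — is fixed. Screening per feature is the classical
pooled-variance Student t test (Welch behind a flag) plus the Gaussian
closed-form Bhattacharyya coefficient
`BC = exp(-D_B)`, `D_B = (μ₁-μ₂)²/(4(σ₁²+σ₂²)) + ½ log(((σ₁²+σ₂²)/2)/(σ₁σ₂))`,
which the tests verify against numerical integration of `∫√(p q)` to 1e-6.
No multiple-testing correction is applied to the radiomic screen — the
screen is a ranking device whose final size is capped downstream, not an
inferential endpoint; significance is strict `p < 0.05`.

The two-phase reduction then (1) collapses parameter variants of the same
base feature by choosing one representative uniformly at random — the only
seeded stage of the screen — and (2) keeps the `k_target` smallest
p-values (ties by feature id) so the radiomic set size matches the genomic
one, reporting the implied p-value threshold.

# Staging models

Five classifier families are supported: Gaussian naive Bayes, linear
soft-margin SVM, k-nearest neighbors (k = 3, Euclidean, deterministic tie
handling), logistic regression, and a CART tree with depth cap 3.
Hyperparameters are config knobs with conventional defaults. The naive
Bayes family is computed by a vectorized internal routine because the
elimination search refits thousands of models; the test suite pins its
predictions to the reference implementation in `e1071`. Logistic
regression uses an unpenalized `glm` fit: a ridge penalty was considered
and rejected because penalized solvers cannot handle the single-feature
subsets that backward elimination legitimately visits, and at ≤ 16
features on ≤ 28 cases the unpenalized fit is deterministic and adequate
(separation inflates coefficients but not predictions).

Feature selection is backward elimination over the pooled genomic +
radiomic set, with both categories competing on equal terms. Every subset
visited is scored by stratified 5-fold cross-validated sensitivity, ties
broken by accuracy — sensitivity first because a missed extra-vesical
tumor (false negative) is clinically costlier than a false alarm. At each
step the feature whose removal degrades the pooled CV score least is
dropped; score ties are broken by removing the weakest univariate feature
(smallest |t|). The final model refits the best recorded subset, where
ties on (sensitivity, accuracy) keep the **larger** subset: the model
retains up to its budget of 8 features per category rather than collapsing
to a single strong predictor, which both matches the capped-selection
design and keeps the selection stable across seeds. Subsets violating the
per-category cap of 8 are never recorded, so the cap holds by
construction. Features are z-scored on the training folds only; external
validation freezes the trained predictor set and scaler.

# The synthetic cohort generator

The generator is the package's study stand-in, and its defaults are the
package's declared study conditions:

* **Cohorts** — 18 intra + 10 extra training cases and 6 + 6 external
  test cases, the sizes of the two-center design this generator emulates. External cohorts reuse the training cohort's planted DEG directions
  and per-gene baseline abundances (that is biology, shared across
  centers) while drawing new patients, masks, library sizes and counts.
* **Volumes** — the mask is a random ellipsoid (semi-axes 22–34% of each
  grid extent) with a smooth boundary perturbation; its size distribution
  is identical for both classes, so volume carries no signal (the tests
  check the class mean size ratio stays within [0.8, 1.25]). Intensities
  inside the mask are smoothed white noise — a cheap stationary Gaussian
  random field whose smoothing radius `0.8(1 + 0.5·effect)` and amplitude
  `0.12(1 + 0.25·effect)` grow with the class effect for extra-vesical
  cases, so correlation length and marginal variance (texture, not size)
  carry the signal. Background voxels are dim noise. None of this is MR
  physics: no bias fields, no coil noise, no partial-volume model —
  passing tests show the pipeline recovers planted texture differences,
  not that it handles scanner artifacts.
* **Counts** — `K ~ NB(mean = s_j q_g 2^{β_g x_j}, dispersion α)` with
  log-normal baselines `q_g` (meanlog log 200, sdlog 1.2, ~10M reads per
  sample across 20k-gene-scale universes), library-size factors
  log-uniform in [0.5, 2] so normalization is genuinely exercised, and
  dispersion 0.1 (typical bulk RNA-seq). Planted DEGs use |log2FC| = 2 by
  default; the nine canonical stage-associated genes (HOXB5, DHRS3, FABP4
  up in low stage; TAGLN2, HIST1H1D, HIST1H2BD, H2AFX, CLDN3, PLAUR up in
  high stage) are always present and, whenever effects are planted at
  all, carry those directions — configurations must therefore plant
  either 0 or ≥ 9 DEGs.
* **Gene sets** — one set seeded with up-in-high genes, one with
  up-in-low genes, the rest random; null configurations make all sets
  random and the truth lists empty.
* **Seeding** — one master seed streams to per-case and per-stage
  sub-seeds by fixed arithmetic, so regeneration is bit-identical and
  appending a case never reshuffles earlier ones.

## Calibrated comparison conditions

The integrated-vs-single-omics benchmark (`run_model_comparison()`) uses
planted effects calibrated once by Monte-Carlo so that each modality alone
is informative but imperfect at the study's sample size (28 training, 12
external test cases): texture effect 0.3 and log2 fold change 0.55 put
both single-omics baselines near 80% test accuracy with partly independent
errors, which is the regime where integrating the two feature families has
measurable headroom. With much stronger effects either baseline saturates
and integration has nothing to add; with much weaker ones the screening
stages cannot find the planted features at n = 28. The benchmark asserts
only the direction of the mean difference over ≥ 20 seeds, never its
magnitude.

## Problem sizes in the test suite

The suite runs the radiomic engine on 16×24×24-voxel volumes with
restricted grids (the full 4612-record sweep is exercised on one case),
null calibrations on 2000 features/genes, and the model benchmark on 20
seeds; these sizes were chosen as the smallest at which the planted-effect
and null-calibration statistics are stable.

# Degenerate inputs and tie-breaks, in one place

* Constant volume → min-max normalization returns all zeros; constant ROI
  → all voxels level 1, first-order `Entropy` 0, `Uniformity` 1.
* Co-occurrence matrix with a single level → `Correlation`, `IMC1`
  inoperable; no valid voxel pairs → whole GLCM block inoperable.
* Ranking ties in enrichment scores → average ranks; dedup ties → seeded
  uniform choice; p-value ties at the count-matching boundary → feature-id
  lexicographic order; elimination ties → weakest |t| first, then feature
  name; fold assignment → per-class round-robin after a seeded shuffle.
* Genes with zero counts in both groups are skipped and flagged; a zero
  group mean gets a continuity floor of half a normalized count so the
  fold change stays finite.

# Known limitations

* The synthetic images are stationary Gaussian fields; real MR texture is
  neither stationary nor Gaussian, and mask delineation noise is not
  modeled.
* The NB Wald test is intentionally unshrunken; do not expect
  DESeq2-grade power at very small n.
* The per-family feature lists are frozen catalog constants; a handful
  of feature names circulating in this literature have no printed
  formula anywhere and are not implemented ("Cluster promin"/"Cluster trend" are
  mapped to ClusterProminence/ClusterTendency as the only plausible
  referents; the unprintable Gaussian-family names are excluded).
* Stage-label vocabulary follows the adopted convention (Ta/Tis/T1/T2
  intra-vesical; T3/T4/N+/M+ extra-vesical); the literature is not
  unanimous on T2, and the package does not attempt to resolve that.
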