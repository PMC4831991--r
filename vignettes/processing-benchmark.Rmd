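---
title: "Processing and benchmarking UHPLC-MS peak tables with peakpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and benchmarking UHPLC-MS peak tables with peakpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(peakpipe)
library(dplyr)
```

## The problem

A non-targeted UHPLC-MS metabolomics experiment yields a peak table:
thousands of metabolite features (m/z–retention-time pairs) measured over
tens of samples, with non-negative intensities and a substantial fraction
of missing cells. Before any univariate or multivariate analysis this
table is *processed*: filtered, normalised per sample, imputed, transformed
element-wise and scaled per feature. Practice varies widely, and the choice
at each stage changes which features an analysis will call biologically
interesting. `peakpipe` implements the common choices at every stage —
2 normalisations × 7 imputation options × 4 transformations × 5 scalings,
a grid of 280 processing permutations — together with a spike-in
benchmarking harness that scores every permutation against known ground
truth, and a synthetic-data generator so the whole machinery is testable
without access to instrument data.

## The data model

A `peak_table` couples a samples × features intensity matrix with feature
metadata (m/z, retention time) and sample metadata (class label, QC flag).
Missing cells are `NA` — an explicit missing marker, never a numeric
sentinel — so pipelines that skip imputation stay well defined: the
univariate screen and NIPALS PCA operate on observed cells only, while
PLS-DA reports such tables as not evaluable rather than silently filling
them. Files use the XCMS export convention (features in rows, leading
`feature_id`, `mz`, `rt` columns); the reader transposes to samples-in-rows
because normalisation is a row operation and scaling a column operation.
Whether zeros denote missing values in an XCMS export depends on the peak
picker's settings, so `read_peak_table(zeros_as_missing = )` makes the
dialect explicit, defaulting to zeros-as-missing.

## What the generator emulates

`generate_peak_table()` draws a two-class serum-style experiment:

* **Design.** 22 + 24 biological samples and 18 pooled-QC injections by
  default — the layout of a randomised two-class human-serum study — and
  3000 features, close to the feature counts that real serum tables carry
  after peak picking. All counts are configurable.
* **Intensities.** Feature intensities are log-normal with base log-means
  uniform on [ln 10^4^, ln 10^7^] (three decades of abundance, so the
  abundance tertiles used by the spike constructor are meaningful). A
  rank-3 latent factor model plus idiosyncratic noise (sd 0.25, log scale)
  gives features correlation structure; each feature loads *positively* on
  exactly one factor (loading magnitude |N(0, 0.20·√3)|), producing the
  positively correlated feature blocks that multi-feature metabolites —
  adducts, isotopologues, co-regulated pathway members — produce in real
  tables. Sign-mixed diffuse loadings would make neighbouring features'
  deviations cancel and neighbour-based imputation uninformative, which
  contradicts the domain. A per-sample multiplicative scale (sd 0.08, log
  scale) models injection-volume and sensitivity drift — the very effect
  normalisation removes.
* **QC samples.** Technical replicates of the pooled mean profile with a
  5 % coefficient of variation: well below the ~45 % biological CV the
  noise levels imply — serum-realistic, and large enough that spikes with
  fold factors near 1 stay insignificant while factor-2 spikes are
  recoverable, as in real two-class serum benchmarks. QCs anchor the PQN
  reference and the glog offset estimate.
* **Null classes.** Class labels are assigned by randomisation and
  re-drawn (up to 20 attempts) until no feature is significant after
  Benjamini–Hochberg adjustment of Mann–Whitney p-values, mirroring how a
  null randomisation is certified in practice; the median fold change
  across features between the classes lies inside [0.8, 1.2].

The noise scales were fixed once, on the grounds above. They matter: the
spiked features are 96 of 3000 (3.2 % of the matrix, as in a realistic
table). At a much smaller feature count the same 96 spikes would dominate
the per-sample totals, distort SUM normalisation and masquerade as false
positives — an artefact of miniaturisation, not a property of the methods.
That is why the generator's default is a realistic feature count and why
the scaled-down datasets used in the test suite reduce the spike count in
proportion.

What the generator does **not** emulate: chromatographic and batch drift,
adduct/isotopologue structure, heavy-tailed per-feature variances, or
MNAR-dominated missingness (an abundance-dependent censoring component is
available via `mnar_weight`, but the default is MCAR, matching the
observation that missingness in filtered tables correlates with neither
m/z, retention time nor response). Passing benchmarks on these data shows
the machinery is correct and reproduces the expected qualitative method
ordering; it does not certify any single permutation as optimal for a
given real dataset.

### Spike-in construction

`construct_modified_dataset()` introduces ground truth: features are split
into abundance tertiles by mean response, 32 per tertile are drawn at
random, and their intensities in the target class are multiplied by a fold
factor from {0.1, 0.2, …, 2.0} ∪ {2.5, 3.0, …, 10.0} (36 values, sampled
without replacement per tertile). Tertiles are rank-based (equal counts)
rather than thirds of the numeric range: with log-normal abundances a
range-based split would leave the top third nearly empty, and a percentile
reading guarantees 32 candidates per block; the range-based variant remains
available via `tertile_method = "range"`. Spiking is applied to the
complete table *before* missingness injection, so the injected missingness
is independent of the spike positions.

## The processing stages

**Normalisation.** `normalise_sum()` divides each sample by its observed
row total and multiplies by 100 (unit: % of total signal). Missing cells
are excluded from the total — the row total of what was measured is the
only total available (a flag treats missing as zero instead).
`normalise_pqn()` builds the reference profile as the per-feature mean over
QC samples, computes each sample's feature-wise quotients against it over
jointly observed features, and divides the sample by its median quotient.
QC samples are normalised the same way as study samples. Without QC
samples the classical per-feature median over all samples serves as
reference (flagged, announced). PQN's median quotient is what makes it
robust when a few features carry genuine large fold changes: those features
move the mean-based SUM factor but not the quotient median.

**Imputation.** Six methods, one contract: every imputer returns a
complete table and never touches an observed cell.

* SV/MN/MD are the constant fills (half the global minimum; per-feature
  mean; per-feature median).
* KNN imputes from the k = 10 nearest *features* (Euclidean distance of
  response profiles). Distances between partially observed features are
  computed over jointly observed samples and rescaled by
  √(n/n~joint~) so that a distance over few shared samples is not
  spuriously small. Within the fixed k-neighbourhood, only neighbours
  observed at the target sample contribute; if none is, the feature's own
  mean is the documented fallback.
* BPCA fits probabilistic PCA with automatic-relevance-determination
  priors by EM, with the latent dimension defaulting to
  min(n, p) − 1 and the ARD penalty pruning unneeded axes. Initialisation
  is the eigendecomposition of the mean-imputed covariance — deterministic,
  so BPCA needs no seed. Convergence is declared when the largest relative
  change of any imputed cell drops below 10^−4^ (default), capped at 200
  sweeps with a warning.
* RF is the missForest scheme: feature-mean start, features visited in
  ascending missing count, each regressed on all others by a random forest
  (100 trees, mtry = ⌊√p⌋, the missForest convention) on its observed
  rows, sweeps repeating until the normalised squared difference between
  successive imputations first increases, at which point the previous
  sweep is returned. The forests are fitted with `ranger` on one thread;
  all randomness flows from the function's seed argument.

`assess_mvi()` is the benchmarking harness for these methods: it
sum-normalises a complete table, masks 10 % of cells completely at random,
runs each method and reports NRMSE — the RMSE over the *masked* cells
divided by the mean of the complete matrix. Averaging over masked cells
only is the informative choice; averaging over all cells would dilute
every method's error toward zero with perfectly "imputed" observed cells.

**Transformation.** glog(y) = ln(y + √(y² + λ)), the natural logarithm,
and the inverse hyperbolic sine (= glog at λ = 1). The glog offset λ is
estimated from technical replicates — the QC samples — as the minimiser of
a Jacobian-normalised replicate-variance objective
J(λ) = SSE(λ)/GM(λ)², where SSE pools the within-feature squared
deviations of transformed QC values and GM is the geometric mean of the
transform derivative over QC cells. The normalisation is essential: the
raw SSE alone is degenerate (λ → ∞ flattens the transform and drives any
variance to zero), while dividing by the squared geometric mean of the
Jacobian makes the objective scale-invariant, giving the equivariance
λ̂(cY) = c²λ̂(Y). The search is a bounded golden-section search on
log₁₀λ spanning min(y)²·10^−4^ to max(y)²·10^4^. λ is estimated on the
table as it stands after normalisation and imputation, since that is the
state in which the transform is applied.

**Scaling.** Feature-wise, over observed cells, with the n−1 standard
deviation throughout: auto ((x−m)/s), Pareto ((x−m)/√s), range
((x−m)/(max−min)), and VAST — autoscaling divided by the coefficient of
variation, i.e. ((x−m)/s)·(m/s), which rewards features with small
relative spread. Zero-spread features become all-zero with a warning
rather than NaN; VAST errors on a zero-mean feature. In every permutation
transformation precedes scaling (the fixed pipeline order is normalise →
impute → transform → scale).

## Statistical engines

The univariate screen excludes QC samples, tests each feature's observed
values between the two classes — Mann–Whitney U (exact null for group
sizes below 8, tie-corrected normal approximation otherwise) or the
pooled-variance Student's t — and adjusts with Benjamini–Hochberg. A
feature with fewer than 3 observed values in either class is not tested
and does not enter the BH family, so sparse features cannot be rescued or
condemned by an imputed constant.

PCA uses NIPALS with all inner products restricted to observed cells and
per-component deflation, making missing values first-class; on complete
data it reproduces the SVD to machine precision (a test asserts 10^−8^).
Component class-separation p-values are computed the way scores plots are
read: Shapiro–Wilk on each class's scores, then a t-test if both look
normal, Mann–Whitney otherwise; QC samples are projected but not tested.

PLS-DA is PLS1 against the centred class indicator. R² is the in-model
fraction of indicator variance explained; Q² = 1 − PRESS/TSS under
stratified, seeded tenfold cross-validation, and the reported component
count maximises Q². PLS-DA demands a complete matrix: with missing cells
the permutation is recorded as not evaluable, which is exactly how
no-imputation pipelines surface in the PLS-DA ranking.

## The benchmark and its rankings

`run_benchmark()` evaluates a grid of permutations against a spiked table.
Normalisation and imputation results are cached across permutations that
share them (an RF imputation is worth reusing); stage failures — e.g. the
natural log of a zero — are captured as failed rows, never aborting the
grid. Outcomes are ranked per analysis mode:

* **Univariate:** true positives (significant ∩ spiked) descending, then
  false positives ascending.
* **PCA:** permutations must show a *fold-change effect* (Spearman
  correlation between |ln factor| and combined PC1/PC2 loading over the
  spiked features positive with p < 0.05) and no *abundance effect*
  (declared when the ten best-ranked spiked features fail to cover all
  three tertiles, or when spiked features' loadings track their
  pre-processing mean abundance, Spearman p < 0.05). Survivors sort by PC1
  score p-value, then PC1+PC2 variance. The "combined" loading is the
  Euclidean norm √(l₁² + l₂²) — the natural magnitude of a feature's
  contribution to the plane; a variance-weighted variant would change
  ranks only when the two components differ greatly in variance, and the
  unweighted form keeps the rank criterion independent of the variance
  criterion it is paired with.
* **PLS-DA:** evaluable rows with R² − Q² < 0.20 (an overfitting guard),
  sorted by R² descending.

All three orders break ties by permutation id, so rankings are total and
reproducible.

## Numerical choices and degenerate inputs

* Missingness injection masks exactly ⌊rate · n~cells~⌋ cells (the target
  is the *total* missing count, so re-injection tops up rather than
  compounds); it refuses to leave a sample or feature fully missing unless
  explicitly allowed.
* The feature filter treats "more than 20 %" strictly: a feature at
  exactly the threshold is retained. Features are filtered before samples;
  QC samples count toward missing fractions by default (flag to exclude).
* Class-absent filling (all-missing in one class, observed in another)
  uses 0.5 × the global minimum and is idempotent.
* BH adjustment, Shapiro–Wilk, Mann–Whitney and the t-test are delegated
  to base R (`p.adjust`, `shapiro.test`, `wilcox.test`, `t.test`); tests
  cross-check `p.adjust` against the brute-force step-up definition.
* NIPALS convergence is relative (10^−9^ on the score vector);
  non-convergence truncates the model with a warning rather than returning
  a half-iterated component.

## Problem sizes in the test suite

The shipped tests and the acceptance script run the full machinery at
reduced scale, chosen as the smallest sizes at which each qualitative
phenomenon is stably expressed: imputation-method comparisons on 24 + 6
samples × 600 features (feature-KNN depends on the neighbour abundance
density of realistically sized tables, and 600 features is where that
regime is reached); the spike-recovery checks on the default
3000-feature benchmark; the grid-ranking checks on a 2 × 7 × 2 × 2
sub-grid over a 400-feature table with 30 spiked features (preserving the
realistic spiked fraction discussed above). Seeds are fixed throughout;
every stochastic stage takes its seed explicitly.

## What the benchmark can and cannot show

Three behaviours of the benchmark deserve explicit framing, because they
are properties of the statistics rather than defects of any pipeline:

* **Zero false positives is not a reproducible guarantee.** BH at
  q < 0.05 *controls the rate*, not the count: once ~90 spiked features
  are discovered, the step-up threshold rises and a handful of null
  features (about 5 % of the discovery count in expectation) will pass in
  a typical run. A benchmark run observing exactly zero false positives
  reflects that dataset's correlation structure and luck, not a property
  of the processing permutation. SUM normalisation additionally transfers
  spike signal into every other feature of the spiked class through the
  row total — the classic SUM fragility, and the reason PQN is preferred.
* **Permuted labels can carry real signal.** On tables with latent
  sample-level factors, a random relabelling can align with a genuine
  factor and earn honest cross-validated predictivity; the Q² estimator's
  own honesty is therefore certified on structure-free tables.
* **RF imputation fills cells with model-consistent predictions**, which
  stabilises PLS-DA cross-validation on these synthetic tables; which
  imputation method minimises R² − Q² is dataset-dependent.

## Known limitations

* PQN assumes the majority of features are unchanged between samples; on
  data where most features shift, the quotient median tracks the shift.
* The BPCA implementation targets imputation quality, not posterior
  inference; its noise-variance update is a maximum-likelihood plug-in
  rather than a full variational posterior.
* Q² from a single tenfold split has fold-assignment noise; rankings near
  the R² − Q² boundary can move between seeds. The seed is part of the
  reported result.
* The generator's null certification (no significant feature after BH) is
  a property of the realised draw, not of the process; extremely small
  sample counts may exhaust the 20 re-randomisation attempts.
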