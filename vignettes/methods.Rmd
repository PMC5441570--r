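---
title: "Methods: stable and predictive connectivity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable and predictive connectivity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstab)
```

`connstab` evaluates functional-network features of a multi-site
case/control fMRI cohort on three axes — univariate significance,
stability across leave-one-subject-out (LOSO) data subsets, and
generalization accuracy for diagnosis and for symptom-severity
prediction. This vignette documents the models, the tunable parameters,
the synthetic test bed, and the numerical and design choices, in that
order.

## Features from thresholded correlation networks

Each sample is one run of one subject: a node-by-time matrix of
BOLD-like signals on a 3-D voxel grid with a binary brain mask.
Per run, a functional network is the matrix of pairwise Pearson
correlations among node time series.

Two feature families are extracted:

* **Voxel-level (log-)degree.** A link joins voxels $i \neq j$ when
  $r_{ij} > c$ with the cutoff $c = 0.7$ by default. The threshold is
  *strict* and *signed*: exactly $r = c$ is not a link, and strong
  negative correlations do not create links unless `absolute = TRUE`
  is requested (after typical preprocessing, negative correlations of
  that magnitude are rare). The degree of a voxel is its link count;
  features are $\log_{10}(\text{degree} + 1)$, a monotone compression
  that tames the heavy right tail of degree distributions. Degrees are
  computed by **tiled accumulation**: correlations are evaluated a
  tile of rows at a time against all nodes and only link counts are
  kept, so the full voxel-pair matrix (which scales as $V^2$) is never
  materialized. Equality with the naive full-matrix computation is
  asserted in the test suite on small grids.
* **Supervoxel link-weights.** The grid is tiled from the origin into
  half-open blocks (default $4 \times 4 \times 3$ voxels); each block
  is a supervoxel whose series is the arithmetic mean of its in-mask
  member series (a plain, order-preserving down-sampling; the
  aggregation rule is not prescribed by the problem, and the mean is
  the standard choice). Blocks whose in-mask fraction falls below
  `min_fill` (default 0.5) are dropped; remaining blocks average over
  in-mask members only. Features are all $n(n-1)/2$ pairwise
  correlations in a fixed lexicographic pair order, used directly —
  no thresholding — so that effect direction is preserved.

Constant time series get correlation 0 with everything (and are
flagged) rather than propagating `NaN`; the diagonal is forced to 1.

**Within-site standardization** (`ss_` feature types) z-transforms
every feature within each acquisition site before samples are pooled:
subtract the within-site mean, divide by the within-site sample SD
(denominator $n-1$, which makes `[1, 2, 3] -> [-1, 0, 1]` exact).
Features constant within a site are set to 0 there and flagged; a site
with a single sample is an error rather than a silent division by zero.

## Mass-univariate testing

Each feature is tested patient-vs-control with the pooled-variance
(Student) two-sample t-test — the null of equal means *and* variances
matches the ranking model, so Welch's correction is deliberately not
used — with two-sided p-values on $n_1 + n_2 - 2$ degrees of freedom
and the sign convention $t > 0 \iff$ patient mean higher. Samples are
*runs*, not subjects; runs of one subject are not independent, which is
a documented caveat of the design and one reason the stability and CV
stages exist. Multiplicity is controlled per feature family at
$\alpha = 0.05$ by Bonferroni ($p < \alpha/m$, strict) and by
Benjamini–Hochberg step-up FDR (the independence-assuming flavor; the
choice of BH over Benjamini–Yekutieli is a design decision, as the
features are positively dependent at worst). Degenerate features (zero
pooled variance) yield $p = 1$ when means agree and $p = 0$ otherwise,
flagged. QC helpers report per-group mean-of-SDs summaries and
one-sample Kolmogorov–Smirnov tests against a normal with estimated
parameters — a Lilliefors-style check whose p-values are conservative,
used as a guide rather than a formal test. `residualize_features()`
projects out nuisance covariates (e.g. motion summaries) via
least squares with an intercept, dropping redundant columns.

## Stability across LOSO folds

One fold per subject leaves out all of that subject's runs. Per fold,
features are ranked by ascending train-only p-value with ties broken by
feature index (a deterministic rule is required for reproducible
intersections). The stability curve records, for each subset size $k$,
the fraction of the top-$k$ set common to *all* folds; it is exactly 1
at $k = N$. The default $k$ grid is powers of 2 up to $2^{14}$ plus 30
(a highlighted operating point for small interpretable link sets) and
$N$. The "stable Bonferroni" set is the all-folds intersection of
Bonferroni survivors; per-fold top-$k$ sets are nested in $k$, and
intersections can only shrink as folds are added — both are asserted as
properties in the tests.

## Classification without double-dipping

LOSO CV over a configurable classifier suite (kNN, linear and RBF SVM,
decision tree, random forest, ridge-regularized logistic regression,
Gaussian naive Bayes, LDA — all via their established R
implementations; the package's own contract is fold construction,
per-fold ranking, and aggregation). For each fold and each $k$, the
classifier trains on the fold's top-$k$ features *ranked on training
rows only* and predicts the held-out subject's runs. Error is the
fraction of misclassified test runs (no majority vote across runs);
FP/FN rates take *patient* as the positive class on their own
denominators, so per-fold error decomposes as
$(\mathrm{FP} \cdot n_{neg} + \mathrm{FN} \cdot n_{pos})/n_{test}$.
The best $k$ is chosen by minimum mean error after all folds complete —
no per-fold peeking. Hyperparameters are fixed sensible defaults
(SVM cost 1, kNN $k$ = 5, 100 trees, ridge $\lambda = 1/n$), exposed in
the config: classifier tuning is not the contribution here, the
protocol is. Logistic regression is fit with a ridge penalty so the
family remains well-defined when $k$ exceeds the sample count.
`double_dip_comparison()` re-runs the identical folds with features
ranked once on *all* rows, quantifying the accuracy inflation that
protocol produces on pure noise.

## Symptom-scale prediction with the elastic net

Integer 0–5 severity scales exist only for patients, so scale
prediction is a patient-only LOSO regression (the subject's scale is
replicated across their runs; predictions are pooled per run). The
model is the elastic net
$\lambda_1 \lVert\beta\rVert_1 + \lambda_2 \lVert\beta\rVert_2^2$ on
site-standardized link-weights, with columns standardized and the
response centered on each fold's training rows. Rather than fixing
$\lambda_1$, the solver searches it (bisection on the log scale with
warm-started `glmnet` paths) for the largest support not exceeding a
target size; this makes results invariant to the solver's internal
penalty normalization ($\lambda_1 = \alpha\lambda$,
$\lambda_2 = (1-\alpha)\lambda/2$ in `glmnet`'s parameterization).
Support size is non-increasing in $\lambda_1$ up to small transient
path jumps, which the search and the tests tolerate at $\pm 1$.

Configurations form a grid — by default 5 target supports
$\{50, 100, 300, 500, 700\}$ × 3 ridge penalties $\{0.01, 0.1, 1\}$
per scale, i.e. 135 entries for 9 scales; the $\lambda_2$ values are a
design choice (only the grid's *size* is prescribed by the study
design). Each configuration is scored by the Spearman correlation
$\rho$ (with its p-value) between pooled held-out predictions and the
true integer scores, plus mean absolute error. Constant predictions
make $\rho$ undefined: the configuration is flagged with $p = 1$.
Bonferroni and FDR flags are computed *jointly over the whole grid*.
The parsimonious rule picks, among FDR-surviving configurations within
5% of the best significant $\rho$, the smallest support (ties: smallest
$\lambda_2$). The stable EN support is the intersection of per-fold
supports of a configuration; it is contained in every fold's support by
construction, which the tests assert. Note the EN-selected links need
not coincide with the lowest-p links of the univariate stage — the two
selections condition on different outcomes (scale vs. diagnosis).

## The synthetic cohort generator

The generator defines the study conditions for every recovery test; its
defaults mirror the emulated cohort: 5 sites, 46 patients + 49
controls (95 subjects, so per-site counts are vectors:
patients 10/9/9/9/9, controls 10/10/10/10/9), 4 runs per subject,
T = 137 time points, an $8 \times 8 \times 6$ voxel grid with
$4 \times 4 \times 3$ blocks.

* **Connectivity model.** Supervoxel latent signals are a zero-mean
  Gaussian process with a compound-symmetric correlation `base_corr`
  (default 0.1) plus `delta_r` (default 0.3) added on the planted
  links for patients — hyperconnectivity, matching the observed
  direction of group differences. No ground-truth brain covariance is
  available, so the simplest controllable structure is used, repaired
  to positive semi-definiteness by eigenvalue clipping and diagonal
  re-normalization (configurations still non-PSD after repair are
  rejected). Each voxel carries `within_share` (default 0.6) of its
  supervoxel latent's variance plus independent noise, so supervoxel
  means inherit the planted structure with mild, computable
  attenuation.
* **Batch effects.** Per site, drawn once: per-voxel additive offsets
  (`site_offset_sd` = 0.5), per-voxel multiplicative gains
  (`exp(N(0, 0.2))`), and the amplitude of a per-run common-mode
  signal added to all voxels (`site_common_sd` = 0.15). Pearson
  correlation is exactly invariant to per-node affine maps, so the
  offset/gain components distort raw signal scale but not
  correlation-derived features; the common-mode component is what
  shifts within-site correlations — a standard scanner common-signal
  model — and makes within-site standardization consequential. The
  true within- vs between-site variance split of real multi-site data
  is unknown; these defaults are stated once here and exposed in the
  config.
* **Subject heterogeneity and scales.** Patients receive a per-subject
  Gaussian perturbation (`subject_link_sd` = 0.1) of the planted-link
  correlations. This is what gives the symptom scales a true
  between-subject signal: each scale's latent is a weighted sum of the
  subject's *realized* mean planted-link weights across runs plus
  noise (`scale_noise_sd` = 0.05), mapped to $\{0, \dots, 5\}$ by
  fixed equal-width binning of the latent's model-implied range
  (mean ± 3 SD, where the SD combines subject heterogeneity, the
  Fisher-approximation sampling variance of a mean-over-runs
  correlation, and scale noise). Equal-width binning preserves
  monotonicity, so Spearman-based recovery is well-posed; a degenerate
  zero-width range maps everyone to the mid-range score 3. The
  model-implied range ignores the small aggregation attenuation and
  site common-mode shift, which off-centers scores by a fraction of an
  SD without affecting monotonicity. Scales are constant across a
  subject's runs, as clinical ratings are per subject.

What the generator does **not** emulate: hemodynamics (no HRF forward
model), head motion, scanner noise spectra, irregular brain-shaped
masks, spatial autocorrelation beyond the block structure, and
subject-level random effects outside the planted links. Passing
recovery tests therefore demonstrates that the *pipeline mechanics* are
correct under a known truth — not that real acquisitions satisfy the
generator's assumptions.

## Numerical choices and degenerate inputs

* Correlations clipped to $[-1, 1]$ after the `tcrossprod` of
  row-standardized series; diagonal forced to 1.
* PSD repair tolerance $10^{-8}$ on the minimum eigenvalue.
* Ties in p-value ranking broken by ascending feature index,
  everywhere.
* Bonferroni is strict (`p < alpha/m`); BH uses `p.adjust`'s step-up
  with `<=`.
* Degenerate t-tests, constant-within-site features, constant scales,
  constant EN predictions, and empty EN supports are all flagged
  rather than erroring mid-pipeline.
* All randomness flows from explicit seeds; child seeds are derived by
  `sample.int` under the parent seed and stay below $2^{31}$. Identical
  configurations yield bit-identical cohorts.

## Problem sizes used by the test and acceptance suites

The suites run the study design at desk scale, chosen so the whole
suite completes in minutes on one CPU: recovery cohorts use 20/20
subjects × 4 runs at T = 137 on a $4^3$ grid with $2^3$ blocks
(8 supervoxels, 28 link features) over 20 seeds; the null-calibration
cohort uses 32 supervoxels (496 links, ≥ 200 features for the binomial
CI); double-dipping uses 40 single-run subjects × 5000 pure-noise
features; the noiseless scale-recovery check lengthens runs to
T = 2000 so per-run link estimates are sharp. The full-size layout
(95 subjects, 380 samples) is exercised for design arithmetic (counts,
folds, chance level) on a small grid, since those quantities do not
depend on grid size.

## Known limitations

* Run-level testing treats correlated runs as exchangeable samples;
  p-values at the univariate stage are optimistic in absolute terms
  (the stability and CV stages are the guard).
* The KS normality check estimates parameters from the data
  (Lilliefors caveat).
* The elastic-net support search assumes approximate monotonicity of
  support size in $\lambda_1$; pathological paths could make the
  "largest support ≤ target" slightly suboptimal, bounded by the
  bisection resolution.
* `read_cohort()` expects one 4-D NIfTI per run already preprocessed
  and registered; no motion correction, filtering, atlas labeling, or
  brain visualization is provided.
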