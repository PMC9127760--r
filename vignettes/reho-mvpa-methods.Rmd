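---
title: "Regional homogeneity MVPA: models, parameters and design notes"
author: "ReHoMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional homogeneity MVPA: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReHoMVPA)
```

# The scientific problem

Depression is among the most common non-motor symptoms of essential
tremor, but no imaging biomarker separates depressed from non-depressed
patients. One candidate measure is *regional homogeneity* (ReHo): the
local temporal coherence of the resting-state BOLD signal, quantified
voxel by voxel as Kendall's coefficient of concordance (W) between a
voxel's time series and those of its 26 face/edge/corner neighbors.
ReHoMVPA implements the full analysis chain that takes spatially
normalized 4D BOLD volumes to (i) individual smoothed, standardized
ReHo maps, (ii) leave-one-subject-out multivariate classification of
diagnostic groups, (iii) permutation-based significance for both
performance and the voxelwise discriminative pattern with
cluster-extent thresholding, and (iv) covariate-adjusted correlation of
cluster means against depression severity. A synthetic cohort generator
with implanted regional coherence makes every stage testable without
clinical data.

# Models and procedures

## Temporal preprocessing

The package assumes spatial preprocessing (slice timing, realignment,
normalization) has been done elsewhere; it implements the temporal
steps, in this order:

1. **Nuisance regression** (`regressConfounds()`): per-voxel OLS
   residualization against an intercept, the Friston-24 expansion of
   the six realignment parameters ($p$, $p^2$, $p_{t-1}$,
   $p_{t-1}^2$), and the white-matter, CSF and whole-brain mean
   signals. Collinear columns are dropped with a warning.
2. **Linear detrending** (`detrendLinear()`): removal of the per-voxel
   first-order polynomial (scanner drift).
3. **Band-pass filtering** (`bandpassFilter()`), default
   0.01–0.08 Hz.

Head motion is summarized by Power's framewise displacement
(`fdPower()`, rotations converted to arc length at 50 mm — the field's
standard radius) and subjects with mean FD above 0.2 mm are excluded
(`excludeByMotion()`; the gate is strictly "greater than").

**Filter design.** Only the pass band is prescribed; the filter family
is an implementation choice. We use the *ideal* (frequency-domain)
zero-phase filter that the standard resting-state toolchains apply:
Fourier components outside the band are removed exactly, and the
in-band component of the linear-trend direction is projected out as
well. The operator is then a symmetric orthogonal projection, which
buys three properties at once: no temporal shift (a shift would
distort the rank structure that Kendall's W measures), exact
idempotence of the detrend → band-pass chain, and attenuation far
beyond the 20 dB contract. The alternative, a forward–backward IIR
filter, meets the attenuation contract but leaves a ~1% second-pass
residual from re-fitted trends; the projection form removes it
entirely.

## Regional homogeneity

For each in-mask voxel, `rehoMap()` computes Kendall's W over $K$
series of $n$ time points,

$$ W = \frac{\sum_i R_i^2 - n \bar R^2}{\tfrac{1}{12} K^2 (n^3 - n)}, $$

where each series is ranked over time, $R_i$ is the across-series sum
of ranks at time point $i$, and $\bar R = (n+1)K/2$. In the interior
$K = 27$ (the voxel plus 26 neighbors). Implementation notes:

* **Mask edges.** $K$ shrinks to 1 + the number of in-mask neighbors;
  discarding edge voxels instead is available via
  `requireFullNeighborhood = TRUE`. We keep edge voxels by default so
  the discriminative surface is not eroded.
* **Ties** take average ranks with no tie-correction term in the
  denominator; BOLD values are continuous so ties are measure-zero.
  Fully constant series sets return 0 with a warning.
* **Vectorization.** Per-voxel rank arrays are summed over the
  3×3×3 neighborhood by separable shift-adds, which is algebraically
  identical to the per-voxel definition; the test suite checks exact
  equality against a literal per-voxel loop.

Each map is then divided by its within-mask mean
(`normalizeGlobalMean()`, in-mask mean exactly 1 afterwards) and
smoothed with a 4 mm FWHM Gaussian (`smoothGaussian()`,
$\sigma_{mm} = \mathrm{FWHM}/\sqrt{8\ln 2}$ per axis, converted to
voxels via the affine). Smoothing is deliberately applied *after* W is
computed — smoothing first would manufacture spurious local coherence.
Convolution is edge-renormalized (field divided by the smoothed
all-ones field), so constant maps are preserved exactly; the output is
re-masked afterwards.

## Classification

`buildFeatures()` turns the smoothed standardized maps into a
subjects × in-mask-voxels matrix (columns in lexicographic (i, j, k)
order, with the inverse mapping retained for weight projection).
`losocv()` runs leave-one-subject-out cross-validation: each fold
mean-centers features using *training-fold statistics only* (the leaky
global variant exists behind `centerWithinFold = FALSE` for
comparison), fits the classifier on $n-1$ subjects and predicts the
held-out one. Classifiers:

* **Linear SVM** (`fitLinearSVM()`), libsvm behind a thin wrapper,
  soft margin $C = 1$ by default (the toolbox convention; exposed as a
  parameter — no tuning is performed, matching the original design).
  The primal weights $f(x) = w_0 + w^\top x$ are recovered from the
  dual coefficients.
* **Gaussian-process classifiers** (`fitGPC()`), binary and
  multiclass: Laplace approximation with a softmax likelihood and
  linear-plus-bias kernel $k(x,x') = x^\top x' + b$ ($b = 1$). The
  binary model is the two-class case of the same code, so a multiclass
  model given two classes degrades gracefully. At the posterior mode
  the latent function is linear in the features, giving exact
  per-class weight maps $w_c = X^\top(y_c - \pi_c)$. Prediction uses
  the softmax of the posterior-mode latent means — a deterministic
  plug-in; expectation propagation and predictive-variance corrections
  are out of scope.

Performance metrics (`performanceMetrics()`): sensitivity,
specificity, PPV, NPV, balanced and total accuracy, and rank-statistic
AUC with ROC coordinates for binary tasks; per-class sensitivity and
total accuracy for the three-class task. Zero-denominator metrics are
reported as `NA` (undefined), never as 0. The positive class for
binary reporting is configurable and logged in every report.

## Permutation inference and discriminative maps

`permutePerformance()` re-runs the *entire* LOSOCV under uniformly
permuted labels (group sizes are preserved by construction) and counts
permutations whose metric is **equal to or higher** than the observed
one; $p$ is that count over the number of permutations, and a zero
count is displayed as $p < 1/n_{perm}$ (e.g. $p < 0.001$ at the
conventional 1,000 permutations) rather than 0. The per-voxel
contribution statistic is the absolute across-fold mean weight of the
run's **unit-norm** weight map; `permuteVoxelWeights()` gives each
voxel the fraction of permuted runs with an equal-or-larger statistic.
The per-run normalization matters: a maximum-margin classifier fits a
well-separated (real) effect with a *small-norm* weight vector — the
norm is inversely proportional to the margin — while permuted labels
give non-separable problems whose dual variables sit at the cost
bound and inflate every raw weight. Comparing raw magnitudes would
therefore favor the null; comparing relative contributions asks where
the discriminative direction points, independent of its scale (the
raw variant remains available via `normalize = FALSE`). `extractClusters()` thresholds the
voxel p-map at $p < \alpha$ (default 0.001), labels connected
components (26-connectivity by default, matching the 27-voxel
neighborhood spirit; 6 and 18 selectable) and keeps components
*strictly larger* than 30 voxels; each cluster is signed by its mean
weight. Whether voxel inference should be two-sided on $|w|$ or
per-sign tail is not standardized; we use $|w|$ and annotate the sign
per cluster.

## ROI–severity correlation

`extractRoiMeans()` averages each subject's smoothed map over every
surviving cluster. `partialPearson()` correlates ROI means with the
(z-transformed, sample-SD convention) severity score after
residualizing both on an intercept plus covariates — age, sex (coded
0/1), education, tremor scores, cognition, anxiety and head motion in
the shipped pipeline — with
$t = r\sqrt{df/(1-r^2)}$, $df = n - k - 2$, two-tailed. With no
covariates this reduces exactly to the plain Pearson test. Bonferroni
control offers two modes because the two counting conventions coexist
in practice: $\alpha/m$ for $m$ ROIs (default) and the pairwise
$\alpha/\binom{m}{2}$ variant; the mode is recorded in the output
table.

# The synthetic cohort generator

`syntheticCohort()` emulates the study conditions end to end: three
groups (depressed tremor patients, non-depressed patients, healthy
controls) of 41/43/45 subjects by default, a 24³ grid of 3 mm voxels,
230 volumes at TR = 2 s, and baseline AR(1) noise (lag-1 coefficient
0.3 — a typical BOLD autocorrelation at TR = 2 s).

* **Implanted coherence.** Inside each configured box, every voxel's
  series is $\sqrt{c}\,s + \sqrt{1-c}\,\varepsilon$, with $s$ a shared
  regional AR(1) course, $\varepsilon$ the voxel's private noise and
  $c$ the group coherence plus a per-subject perturbation
  $\delta \sim N(0, 0.05^2)$. Kendall's W rises monotonically with
  $c$; $c=0$ leaves pure noise.
* **Clinical covariates** are drawn independently per scale from
  normals with the published group means/SDs, floored at 0, with
  depression scores floored at 7 for the depressed group. Floored
  scales use *mean-matched* truncated normals: the location parameter
  is solved so the post-truncation mean equals the target (naive
  truncation of N(18.98, 6.35²) at 7 would inflate the mean by ~0.4).
  Only the printed moments are known, so independence between
  covariates is assumed and documented; real clinical scales are
  correlated, which this generator does not emulate.
* **Severity coupling.** A region's `hdrsCoupling` adds
  $\kappa\,\delta$ to the depression score, so partial-correlation
  recovery is testable with known sign and the clamp at the floor is
  rarely active.
* **Head motion** is uniform on [0.05, 0.18] mm so every subject
  passes the 0.2 mm gate by default; `highMotion` injects subjects
  above the gate to exercise exclusion.
* Tremor scales are undefined (NA) for healthy controls, as in the
  emulated cohort table; downstream correlation uses patients only.

What passing tests on this generator do **not** show: robustness to
scanner artifacts, anatomy, spatial misregistration, correlated
covariates, or non-AR(1) physiological noise — none of which are
simulated. The generator validates the *computational* chain, not
clinical generalization; the published headline accuracies belong to
the authors' clinical cohort and are not reproducible from simulation.

# Numerical choices

* Kendall's W uses exact integer/half-integer rank arithmetic; the
  map path and a literal loop agree bitwise.
* The normalized stage pins the in-mask mean to exactly 1 (guarding
  the class invariant against last-ulp rounding).
* GPC Newton iterations stop when the latent values move < 1e-6
  (probability-scale effects ≪ 1e-6) and error out with diagnostics
  after 200 iterations; the kernel carries a relative 1e-8 jitter.
* Cluster labeling breaks ties deterministically (components ordered
  by size; voxels in sorted linear order), and all grid coordinates
  are reported both 0-based and in mm via the affine to avoid
  indexing ambiguity.
* The permutation RNG is seeded explicitly and the seed is recorded in
  every result object and report.

# Problem sizes in the shipped checks

The validation suite runs, by design, at sizes a desk machine handles
comfortably: oracle equivalence on 1,000 random (K, n) instances and
an 8³×40 volume; classification recovery on 15+15 subjects at the full
24³ grid and 230 volumes with one implanted 6³ box (coherence 0.8 vs
0.1, and an equal-coherence null); permutation calibration on 100
null cohorts × 200 permutations at a reduced 4³ grid with 7+7
subjects (small enough for the full-relabeling loop to stay cheap,
large enough that the discrete accuracy distribution has enough
distinct values for a meaningful tail probability);
discriminative-map localization at 60 permutations with the minimal
attainable voxel p; and severity-coupling recovery over 100 cohorts of
16 patients at a 9³ grid. The published-scale settings (1,000
permutations, full cohort) remain the defaults of the user-facing
functions.

# Known limitations

* Expectation-propagation GPC, nonlinear kernels, feature selection
  and hyperparameter search are out of scope (none were used in the
  emulated analysis; multiple-kernel learning is deliberately
  omitted).
* No parametric (random-field) cluster inference and no voxelwise FDR:
  inference is permutation + extent only.
* Surface-based and 7/19-neighbor ReHo variants and frequency-specific
  ReHo are not implemented.
* The pipeline reads spatially normalized NIfTI-1 volumes; DICOM and
  BIDS layouts are not parsed.
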