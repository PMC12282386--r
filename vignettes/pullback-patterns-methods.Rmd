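---
title: "Methods: classifying physiological CAD patterns from virtual pullbacks"
author: "PullbackPatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying physiological CAD patterns from virtual pullbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PullbackPatterns)
```

## The problem

Fractional-flow-reserve-like pressure ratios can now be derived from a
single angiographic view (the Murray's law-based quantitative flow ratio,
muFR), yielding a *virtual pullback*: the pressure ratio as a function of
distance from the vessel ostium, sampled every 0.35 mm. The longitudinal
shape of that curve carries clinically actionable information — whether
coronary artery disease is **focal** (one short abrupt drop, a good
stenting target), **diffuse** (a gradual vessel-wide decline), **mixed**,
or **serial** (two or more focal drops separated by more than 20 mm of
healthy vessel). Visual interpretation of these patterns has poor
inter-observer reproducibility, so this package implements a quantitative
pipeline: per-vessel physiological indices, functional-shape features via
multivariate functional PCA (MFPCA), and supervised classifiers evaluated
by repeated train/test resampling.

The input is always a sampled curve; computing muFR from angiographic
images is out of scope.

## Per-vessel indices

All drop and gradient computations run on the *monotonized* curve — the
least-squares non-increasing projection (pool adjacent violators via
`stats::isoreg`). A pressure ratio cannot physically rise along a
pullback, so non-monotone wiggles are treated as trace noise. The raw
curve is preserved for the functional analysis, where shape noise is
informative variance rather than an artefact. Monotonization is
idempotent, and on noise-free monotone inputs every index below is exact.

The **pullback pressure gradient index** is

$$\mathrm{PPGi} = \frac{1}{2}\left(
  \frac{\mathrm{MaxPPG}_{20\,\mathrm{mm}}}{\Delta\mu\mathrm{FR}_{vessel}}
  + \left(1 - \frac{L_{disease}}{L_{total}}\right)\right),$$

combining the fraction of the whole vessel drop concentrated in the worst
20-mm window with the fraction of vessel free of functional disease.
Values near 1 indicate focal, near 0 diffuse disease; the validated
dichotomization cut-off is 0.78 (focal when PPGi ≥ 0.78). Conventions:

* $\Delta\mu\mathrm{FR}_{vessel}$ is the proximal-minus-distal endpoint
  difference, not max-minus-min: virtual pullbacks start at the
  normalized proximal value, so the endpoints are the physiologically
  meaningful anchors.
* The 20-mm window is discretized to $\lfloor 20/0.35\rfloor = 57$ grid
  steps (19.95 mm). Curves shorter than the window return the
  whole-vessel drop, making the first bracketed term 1.
* $L_{disease}$ is not defined operationally in the literature we
  follow; we define it as the total length of grid segments whose local
  monotonized gradient is at least a **disease floor** of 0.001/mm — an
  order of magnitude below the 0.025/mm major-gradient cut-off. A
  segment losing less than 0.001 muFR per mm (0.08 over an 80-mm vessel)
  is functionally healthy for any practical purpose. The floor is a
  configurable argument of `functionalDiseaseLength()` and
  `computePpgi()`.
* The index is undefined (an error) on a zero-drop curve; such vessels
  have distal muFR near 1 and should already have been excluded by the
  "no functional disease" rule below.

The **local gradient** dmuFR/ds is the maximum negative first difference
of the smoothed monotonized curve divided by the spacing; smoothing is a
centered moving average spanning 2 mm (5 grid points at 0.35 mm), which
reproduces linear slopes exactly while suppressing single-sample jitter.
A gradient of at least 0.025/mm flags a *major gradient*. Whether the
per-vessel summary should be the maximum or some other functional of the
local gradient is not stated in the source literature; we use the
maximum, which is the natural reading of "presence of a major gradient".

Threshold conventions follow the printed inclusivities throughout:
focal when PPGi ≥ 0.78; major gradient when ≥ 0.025/mm; hemodynamically
significant when distal muFR ≤ 0.80; excluded as disease-free when
distal muFR > 0.95.

## MFPCA features

Vessels differ in length, so curves are registered by linearly rescaling
each domain to $[0,1]$ and interpolating onto a common 101-point grid.
Registration is a per-vessel operation and leaks nothing across vessels.
PPGi is length-sensitive and is always computed on the physical grid;
the shape analysis need not be, and normalized-domain registration keeps
lesion position a relative (shape) property. The registered variables
are the muFR curve and the minimal-lumen-diameter curve; which diameter
curve(s) entered the original analysis is not stated, so MLD is the
default and RVD can be added via `registerCurves(variables = )`. RVD
information enters the classifiers separately as the scalar reference
diameter.

The MFPCA estimator is the standard two-stage score-combination
construction:

1. per variable, a Karhunen–Loève expansion: center by the pointwise
   mean, eigendecompose the quadrature-weighted sample covariance
   (trapezoid weights), and keep the smallest number of components
   reaching 99% of variance;
2. stack the per-variable score vectors and eigendecompose their
   covariance; the eigenvectors form the combination matrix, the
   eigenvalues are the multivariate eigenvalues, and multivariate
   eigenfunctions are the univariate ones combined blockwise.

Multivariate eigenfunctions are orthonormal under the summed
per-variable quadrature inner product by construction; training scores
are uncorrelated with variances equal to the eigenvalues. With one
variable, a uniform grid and unit weights the scores coincide with
matrix PCA scores — the oracle used in the test suite. Three multivariate
components are retained, matching the three score features the
classifiers consume. Neither variable is re-weighted (no weighting
scheme is given in the source); eigenfunction signs are fixed by a
non-negative weighted integral, ties broken toward a positive first
loading. The univariate truncation level (`pve = 0.99`) and the grid
size (101) are exposed as arguments.

Sparse/irregular-designs FPCA (PACE-style conditional scores) and
penalized basis smoothing are out of scope: virtual pullbacks are
densely and regularly sampled by construction.

## Feature sets and classifiers

The **muFR model** uses 12 features: age (years), sex (male = 1),
smoking status (3 levels, encoded as two indicators against the
non-smoker baseline), diabetes, dyslipidaemia and hypertension flags,
the three MFPCA scores, the reference diameter (mm), the distal muFR
and dmuFR/ds. The **PPGi model** appends PPGi as the 13th feature. A
missing covariate is an error; nothing is imputed.

The penalized logistic classifier is the elastic net (implemented on
glmnet): standardized features, penalty
$\lambda[\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2]$, a 100-point
log-spaced $\lambda$ grid descending four decades from the smallest
all-slopes-zero penalty, and $\lambda$ chosen by stratified 10-fold
cross-validated deviance. The mixing parameter is unreported in the
source; $\alpha = 0.5$ is the default and both $\alpha$ and the
min-vs-1SE selection rule are arguments. Three-class problems use the
symmetric multinomial likelihood rather than one-vs-rest fitting;
one-vs-rest appears only in the ROC analysis. Binary prediction
thresholds probabilities at 0.5 (no threshold tuning is described);
multiclass prediction is the argmax.

The random forest uses 500 trees and $\sqrt{p}$ candidate features per
split — the conventional defaults, since no tuning is described — with
out-of-bag probability estimates available from the fit. Class-imbalance
reweighting, boosting, calibration and post-hoc explanation methods are
deliberately out of scope.

## Evaluation protocol

`repeatEvaluate()` repeats, for each iteration $i$ with seed
$\mathrm{base} + i$ (so any iteration is reproducible in isolation):

1. a 75% stratified split. Stratification uses the full four-class
   pattern label with per-stratum training size
   `roundHalfUp(0.75 n)`; at the reference class mix this yields exactly
   176/58 of 234 (focal vs diffuse) and 258/85 of 343 vessels. Test sets
   missing a task class are re-drawn, with the count reported.
2. MFPCA refitted **on the training vessels only**, then applied to all;
   feature standardization likewise happens inside the classifier fit.
   The source does not state this explicitly, but any other choice leaks
   test information into the features and invalidates the test metrics;
   a regression test corrupts test labels and asserts unchanged
   predictions.
3. classifier fitting and held-out scoring: accuracy, sensitivity,
   specificity, PPV, NPV (zero-denominator ratios are `NA`, never 0) and
   AUC by the tie-corrected Mann–Whitney rank formula. The three-class
   task reports per-class sensitivity/specificity and one-vs-rest AUCs.
   The PPGi cut-off rule produces no probability scores, so its AUC is
   `NA` by design.

Summaries are per-metric means with 95% percentile (2.5/97.5) intervals
across iterations; the CI method is not named in the source, and a
normal-approximation option exists internally for comparison. Binary
task definitions: focal vs diffuse restricts to those two classes;
focal vs non-focal pools diffuse, mixed and serial; the three-class task
pools mixed and serial into "others" (serial alone is too rare to be its
own class). Percentages print with half-away-from-zero rounding, the
clinical convention (52.5% → 53%).

## The synthetic cohort

The study's angiograms are not deposited, so `simulateCohort()`
generates the cohort every analysis runs on. A vessel is

$$\mu\mathrm{FR}(s) = 1 - \sum_k d_k\,\sigma\!\left(\frac{s - c_k}{w_k / (2\ln 19)}\right)
  - b\,s + \varepsilon(s),$$

sigmoidal lesion drops (depth $d_k$, center $c_k$; the width $w_k$ is
the distance containing 90% of the drop, hence the $2\ln 19$ scale) plus
a linear diffuse slope $b$, clipped to $[0,1]$ and sampled every
0.35 mm. The noise $\varepsilon$ is moving-average-filtered white noise
(sd 0.005 by default), mimicking correlated trace wobble rather than
i.i.d. jitter, with its envelope tapered to zero over the first and last
3 mm so the proximal normalization (muFR = 1) and the distal guarantee
survive. If the deterministic distal drop is under 0.055 the profile is
rescaled up, guaranteeing distal muFR ≤ 0.945 < 0.95 — generated vessels
are never excludable as disease-free. Diameter curves taper linearly
from the proximal reference diameter with Gaussian-shaped narrowings
under the lesions.

Class archetypes enforce the consensus definitions (focal: exactly one
lesion, width ≤ 20 mm, drop ≥ 0.05; serial: ≥ 2 lesions separated by
> 20 mm of healthy segment; diffuse: positive slope, no lesion; mixed:
both). Default parameter distributions were fixed once from the
reference cohort's reported marginals: class mix 160/74/82/27
(focal/diffuse/mixed/serial; the table's 27-of-343 count is used where
the running text says 8%), focal lesion depth ~ N(0.29, 0.16) truncated
to [0.05, 0.70] (so focal distal muFR ≈ 0.71 ± 0.16), diffuse total drop
~ N(0.18, 0.08) truncated (distal ≈ 0.82 ± 0.08), vessel length uniform
40–120 mm, proximal diameter ~ N(3.61, 0.66) truncated positive, and
class-conditional covariate marginals (sex, smoking, hypertension,
diabetes, dyslipidaemia, age — diffuse patients older at 68 ± 11 vs
58 ± 13 for focal) taken from the reported per-class counts. Focal
vessels also receive a mild background taper (uniform up to 0.0008/mm,
below the disease floor) so the 20-mm-window term is not degenerately 1.
Each vessel gets its own synthetic patient; the reference cohort's
occasional multi-vessel patients are not emulated, which only matters
for analyses clustering on patient.

What the generator does **not** emulate: hemodynamic mechanism (no flow
equations), realistic lesion co-location between the muFR and diameter
curves beyond a monotone link, inter-rater psychology beyond a
confusion-hub error model (raters err toward "mixed"; a second
adjudication round is emulated as convergence to ground truth, since no
algorithmic description of divergence resolution exists), and the
longer diffuse-PPGi tail of real cohorts: with a strictly linear diffuse
decline, synthetic diffuse vessels sit lower on the PPGi scale than the
reported diffuse mean. Passing tests therefore demonstrate internal
correctness and the qualitative ordering of methods (PPGi-augmented
models dominate; the cut-off rule trades sensitivity for specificity),
not the reported clinical effect sizes — those depend on the undeposited
data.

## Numerical choices and degenerate inputs

* Resampling grids contain $\lfloor L/h\rfloor + 1$ points at exactly
  the requested spacing $h$; a trailing remainder shorter than one
  spacing is dropped.
* `monotonize` clips to $[0,1]$ after projection; already-monotone
  input is returned untouched.
* Eigenvalues are clamped at 0 (numerical negatives), and requesting
  more multivariate components than available scores truncates with a
  warning.
* Constant feature columns are dropped with a warning before the
  elastic-net fit; a single-class response is an error everywhere.
* Stratified splitting requires at least 2 members per stratum and
  always keeps both sides of a stratum non-empty.
* Seeded helpers save and restore the caller's RNG state, so library
  calls never clobber a session's random stream.

## Problem sizes

The test suite and the acceptance script run the full pipeline on a
343-vessel synthetic cohort at 50 split iterations (25 for the
three-class forest), 1,000 random curves for the window-scan oracle,
and 200-subject samples for the PCA equivalence — sizes chosen so the
whole suite completes in a few minutes on one CPU while keeping every
Monte-Carlo margin comfortable.

## Limitations

PPGi's disease-length term rests on a package-defined operationalization
(the 0.001/mm floor); results are insensitive to it on focal/diffuse
archetypes but genuinely borderline vessels will move with the floor.
The elastic-net mixing and tuning rule are assumptions where the source
is silent. Synthetic performance numbers are optimistic relative to
clinical data — the generator's classes are cleaner than expert-panel
labels — and should be read as ordering evidence only.
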