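# PullbackPatterns

Classification of physiological patterns of coronary artery disease
(CAD) from angiography-derived virtual pullback curves.

Angiography-derived pressure ratios such as the Murray's law-based
quantitative flow ratio (muFR) provide, from a single angiographic view,
a *virtual pullback*: the pressure ratio plotted along the vessel,
sampled every 0.35 mm. The longitudinal shape of that curve decides
whether disease is **focal** (one short abrupt drop — a good target for
stenting), **diffuse** (a gradual vessel-wide decline), **mixed**, or
**serial**. This package is for interventional-cardiology and
biostatistics researchers who want that interpretation to be
quantitative and reproducible rather than visual.

It implements, in one pipeline:

* **Per-vessel physiology** — the pullback pressure gradient index

  PPGi = ( MaxPPG₂₀ₘₘ / ΔμFR_vessel + (1 − L_disease / L_total) ) / 2,

  with the validated focal/diffuse cut-off (PPGi ≥ 0.78 → focal), the
  local gradient dμFR/ds with its 0.025/mm major-gradient cut-off, the
  ≤ 0.80 hemodynamic-significance rule and the > 0.95 disease-free
  exclusion rule. All drops are measured on the least-squares
  non-increasing projection of the trace.
* **Functional shape features** — multivariate functional principal
  component analysis (MFPCA) of the co-registered (muFR, lumen
  diameter) curve pair, yielding three score features.
* **Classifiers** — elastic-net penalized logistic regression and a
  random forest over a 12-feature set (demographics, MFPCA scores,
  reference diameter, distal muFR, dμFR/ds) and its 13-feature
  extension that adds PPGi.
* **Evaluation** — repeated stratified 75/25 resampling with
  leakage-free refitting, confusion metrics, binary and one-vs-rest
  ROC/AUC, and percentile confidence intervals.
* **A synthetic cohort generator** — labelled vessels with
  focal/diffuse/mixed/serial morphology at the reference class mix and
  covariate marginals, plus an eight-rater consensus-labelling
  emulator, so the whole pipeline runs without clinical data.

## Worked example

```r
library(PullbackPatterns)

coh <- simulateCohort(343, seed = 1)
coh
#> VesselCohort: 343 vessels (focal 167, diffuse 68, mixed 79, serial 29)

idx <- cohortIndices(coh)
round(tapply(idx$ppgi, patternLabel(coh), mean), 2)
#> diffuse   focal   mixed  serial
#>    0.46    0.82    0.63    0.66

rec <- vesselRecords(coh)[[1]]
computePpgi(pullbackCurve(rec))
#> PPGi 0.803  [max 20-mm drop 0.180 / vessel drop 0.212; diseased 17.1 of 70.7 mm]

rep <- repeatEvaluate(coh, "focal_vs_diffuse", "ppgi_cutoff",
                      nIterations = 20, baseSeed = 1)
rep
#> EvaluationReport: focal_vs_diffuse / ppgi_cutoff, 20 iterations (0 re-drawn)
#>       metric  mean ci_lower ci_upper
#>     accuracy 0.853    0.778    0.890
#>  sensitivity 0.793    0.688    0.846
#>  specificity 1.000    1.000    1.000
#>          ppv 1.000    1.000    1.000
#>          npv 0.665    0.567    0.725
#>          auc    NA       NA       NA
```

Reading the output: focal vessels concentrate their pressure drop
(mean PPGi 0.82, above the 0.78 cut-off) while diffuse vessels spread it
(0.46). Vessel V001 has 85% of its 0.21 drop inside the worst 20-mm
window and three quarters of its length disease-free, hence PPGi 0.80 —
focal by the cut-off. Over 20 random 75/25 splits the cut-off rule is
highly specific for diffuse disease (1.00) but misses a fifth of focal
vessels (sensitivity 0.79); it produces no probability scores, so no
AUC. Fitting the penalized-logistic models instead
(`method = "penalized_logistic"`, with `includePpgi = TRUE/FALSE`)
shows the PPGi-augmented feature set dominating the 12-feature model —
the ordering the evaluation harness is designed to expose.

A thin command-line wrapper over the same functions
(`inst/scripts/pullback-patterns`) provides `simulate`, `features`,
`train`, `evaluate` and `classify` subcommands for shell pipelines.

## Documentation

The methods vignette
(`vignettes/pullback-patterns-methods.Rmd`) documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, and the package's
numerical conventions.
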