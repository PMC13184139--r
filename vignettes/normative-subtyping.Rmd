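---
title: "Normative modeling and deviation-based subtyping of regional homogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling and deviation-based subtyping of regional homogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehonorm)
```

## The problem

Case–control comparisons of resting-state fMRI average over patients and so
erase the heterogeneity that matters for stratified psychiatry. Normative
modeling reverses the logic: a reference model of a brain feature as a
function of age and sex is fitted in healthy controls (HC), and each patient
is scored by how far they deviate from the reference — a growth-chart for
brain function. `rehonorm` implements this program for regional homogeneity
(ReHo), a voxel-wise measure of local temporal synchrony, reduced to 246
atlas regions, and then stratifies patients by clustering their deviation
profiles.

The pipeline is: ReHo extraction → multi-site harmonization → per-region
Gaussian-process normative models → Z-deviation maps → deviation statistics
→ k-means subtyping → stability validation. Every stage runs on the
package's synthetic cohort generator, so the whole analysis is reproducible
on a desk without any imaging data.

## ReHo as Kendall's W

For K time series over n time points (a voxel and its neighbors), each
series is ranked over time and

$$W = \frac{\sum_i R_i^2 - n \bar R^2}{K^2(n^3 - n)/12},$$

with $R_i$ the rank sum across series at time point $i$. Midranks are used
for ties and no tie-correction factor is applied, matching the classic ReHo
convention; a constant (all-tied) series therefore contributes no apparent
synchrony, and a fully constant neighborhood has $W = 0$ rather than
appearing perfectly synchronized. The default neighborhood is the full
3×3×3 cube (27 voxels), the most common ReHo convention; 7 (faces) and 19
(faces + edges) are also available. Voxels with fewer than two in-mask
neighbors are reported absent rather than extrapolated. Regional values are
plain means of valid voxels per atlas label.

## Site harmonization

Multi-site data carry additive and multiplicative scanner effects.
`fit_combat()`/`apply_combat()` implement parametric empirical-Bayes
location/scale harmonization: each region is standardized by its covariate
fit (age, sex) and pooled variance; per-site locations $\gamma_{sr}$ and
scales $\delta^2_{sr}$ are estimated on the standardized residuals and
shrunk across regions (normal prior for $\gamma$, inverse-gamma for
$\delta^2$) by the standard iterative conditional scheme. The default
convergence tolerance is `1e-6` (relative change, capped at 100
iterations); the canonical neuroimaging implementation stops at `1e-4`, and
passing `tol = 1e-4` reproduces it to machine precision, which is how the
package's oracle-equivalence test is configured.

Two deliberate design choices:

* **Shrinkage and idempotence.** Empirical-Bayes ComBat is *not* an exact
  fixed point: the shrunken $\gamma^*$ differs from the raw per-site mean,
  so a second pass changes the data slightly. The no-shrinkage variant
  (`eb = FALSE`) with no covariates *is* an exact fixed point, and that is
  the configuration under which the package asserts idempotence.
* **Diagnosis in the design.** Harmonization is fitted on HC and patients
  jointly with age and sex preserved; diagnosis is *not* protected by
  default (avoiding any leak of diagnosis into the harmonization target)
  but can be added via `harmonize_diagnosis = TRUE` in the pipeline
  configuration.

Because the priors are estimated across regions, harmonization should be
fitted on the full 246-region matrix even when later stages only use a
subset; with very few regions the shrinkage targets are noisy and residual
per-site scale differences fatten the tails of downstream Z-scores.

## The normative model

One independent Gaussian-process regression per region models ReHo as a
function of age and sex. The kernel is a sum of

* a squared-exponential over standardized age — smooth nonlinear lifespan
  trends (units: ReHo² signal variance; length-scale in age SDs, default
  initialized at 1);
* a linear kernel over (standardized age, sex) — linear drift and an
  additive sex offset (sex coded 0/1);
* white noise $\sigma^2_n$.

Hyperparameters maximize the log marginal likelihood by L-BFGS-B with
analytic gradients in log-parameter space, with a data-driven first start
(half the target variance on signal and noise) plus jittered restarts
(default 2). Targets are centered on the training mean, so no explicit mean
function is needed.

A subject's deviation is
$$Z = \frac{y - \mu(x)}{\sqrt{\sigma^2_f(x) + \sigma^2_n}},$$
where $\sigma^2_f$ is the latent predictive variance. Extreme deviations
use the strict inequality $|Z| > 2.6$ (one-sided normal tail $< 0.005$); a
value exactly at the threshold is not extreme. Patient deviations are
computed from models trained on all HC; HC deviations come from held-out
folds of the 10-fold cross-validation so that no subject is scored by a
model that saw them. Model accuracy is summarized per region by SMSE (test
MSE over test variance; 1 ≈ predicting the mean) and MSLL (mean Gaussian
negative log predictive density minus the trivial train-mean/variance
model; negative is better).

Predicted regional trajectories can be grouped with
`cluster_trajectories()`: curves on an age grid are standardized and
2-means-partitioned; the cluster rising from start to end is labeled
"increasing". This reproduces the familiar split into regions whose local
synchrony rises with age and regions where it falls.

## Deviation summaries and statistics

Deviation indices are mean-based: overall = mean Z over regions, positive =
mean of $\max(Z, 0)$, negative = mean of $\min(Z, 0)$, so
overall = positive + negative holds exactly and the indices are
scale-free in the number of regions. Extreme counts, per-region overlap
percentages, and cohort prevalences follow directly. Group comparisons use
Welch's t (robust to site-driven variance heterogeneity) with pooled-SD
Cohen's d, one-way ANOVA with partial $\eta^2$, type-III ANCOVA with a
factor×covariate interaction (sum-to-zero contrasts), Cramer's V from the
uncorrected $\chi^2$, Pearson's r, and Benjamini–Hochberg FDR adjustment.

## Subtyping and validation

Patients are clustered on their 246-region Z maps (network aggregation is
descriptive only). k-means uses k-means++ initialization with 50 restarts,
keeping the solution with the lowest within-cluster sum of squares. The
number of clusters is chosen by majority vote over an 11-index validity
battery — silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn, gap
statistic (one-standard-error rule, 10 uniform reference draws), Hartigan
(smallest k with H ≤ 10), Krzanowski–Lai, C-index, McClain–Rao,
Ratkowsky–Lance, and Ball–Hall (largest successive drop) — with ties broken
toward the smallest k.

Stability is assessed by (i) leave-one-site-out reclustering, aligning each
fold's labels to the primary labels by exact optimal assignment over
cluster renamings and reporting the percent agreement (overlap rate);
(ii) subgroup reruns (male, female, young/old split at the cohort median
age — the split point is a package choice since no standard cut exists —
FEDN, recurrent, medicated) with overlap rates and the adjusted Rand index;
and (iii) a minimum-site-size filter (default 10 subjects; a stricter
30-patient filter can be applied before reclustering). Folds in which
k-means cannot produce k non-empty clusters are recorded as failed rather
than dropped.

## The synthetic cohort generator

The generator defines the study conditions under which the package is
exercised:

* 246 regions partitioned over 8 networks (FPCN, VAN, DMN, LN, DAN, SMN,
  VN, SUB; at least 10 regions each); half the regions increase with age,
  half decrease.
* Trajectories $f_r(age) = a + b\,(age-40) + c\,(age-40)^2$ with slopes of
  0.005–0.03 ReHo units per decade, curvature bounded to preserve
  monotonicity, and sex offsets of SD 0.01 — the simplest form exhibiting
  the nonlinearity the GP must capture.
* Site effects follow the ComBat generative model exactly (additive
  location per site×region, SD 0.05; multiplicative noise scale per
  site×region in 0.8–1.25), so harmonization is exactly testable.
* Residual noise SD 0.08 ReHo units.
* Two patient subtypes at a 36/64 split with opposing network-level Z
  shifts of between-subtype Cohen's d: FPCN −1.75, VAN −1.20, DMN −0.90,
  LN −0.40 (transmodal, subtype 1 down) and DAN +1.00, SMN +1.81, VN +0.52
  (unimodal, subtype 1 up); SUB carries no planted effect.
* Clinical variables with planted subtype differences (age d = −0.19,
  HAMD-17 total d = 0.17, anxiety/somatization d = −0.15, insight item
  d = −0.25, medication rates 0.55 vs 0.642 giving Cramer's V ≈ 0.09) and a
  duration–severity correlation of −0.21 induced in subtype 1 only through
  a shared latent factor. Scores are drawn on their valid ranges by
  clipping, which mildly attenuates planted effects — tests account for
  this.
* Default cohort sizes mirror a large multi-site study (1011 HC, 1101
  patients, 22 sites); all tests and examples run at reduced n for
  desk-scale runtime.

`simulate_deviation_maps()` draws patient Z maps directly (unit normal
noise plus the subtype shifts), which is the natural input scale for the
subtyping stage and makes clustering experiments cheap.

What the generator does **not** emulate: BOLD physiology, head motion,
preprocessing artifacts, spatial autocorrelation between neighboring
regions, non-Gaussian site effects, or realistic site-demographic
confounding. Passing tests therefore demonstrate the correctness and
calibration of the *procedures* under their stated assumptions, not
performance on real multi-site clinical data.

## Numerical choices and problem sizes

* GP kernels get a `1e-10` diagonal jitter; failed Cholesky factorizations
  score a start as infeasible instead of aborting; optimizer bounds are
  `exp(±15)` on each hyperparameter, 100 L-BFGS-B iterations.
* Cross-validated calibration is checked at 500 HC over 21 regions spread
  across the atlas (10-fold, one optimizer start), where held-out Z-scores
  show mean ≈ 0, variance ≈ 1, and an extreme rate within half a percentage
  point of the theoretical 0.93%.
* Subtyping experiments use 600 patients over 6 sites — large enough for
  the 36/64 split to be estimated to ±2% and small enough to cluster in
  seconds.
* k-means ties (identical objective) resolve to the first restart that
  attained the optimum; all randomness flows from explicit seeds, and the
  pipeline derives per-stage seeds from one root seed.
* Degenerate inputs error early and name the offending field: single-site
  harmonization, constant-age covariates, all-flat trajectory sets, empty
  index batteries, tables filtered to nothing.

## Limitations

Per-region GPs ignore spatial covariance between regions (no multi-task
sharing); the Gaussian likelihood cannot produce warped, skewed normative
distributions; the index battery is a representative stand-in, not a
reimplementation of any specific package's 23 indices; and the run manifest
records checksums and timings but does not implement resume-from-cache.
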