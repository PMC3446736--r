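---
title: "Methods: region-level and voxel-level association models with permutation cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level and voxel-level association models with permutation cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmperm)
```

## The scientific problem

`vbmperm` implements a two-resolution analysis of how a subject-level
exposure — in the motivating application, a factor-based social-engagement
score in a cohort of older men — relates to structural brain volumes:

1. **Region-of-interest (ROI) models.** For each of 20 predefined
   anatomical regions (total brain, total gray and white matter, four
   lobar subdivisions of each tissue class, and nine smaller structures),
   an ordinary least squares regression of the region volume on the
   exposure, adjusted for a fixed covariate set.  Standardized
   coefficients make effects comparable across regions of very different
   size.
2. **Voxel-based morphometry (VBM).** A mass-univariate general linear
   model at every voxel of spatially normalized tissue-density maps,
   thresholded into suprathreshold clusters whose multiplicity-adjusted
   significance comes from a max-cluster-size permutation test.

A third, *temporal-reversal* analysis regresses the exposure on the
five-year change in each region volume, probing whether shrinking
volumes predict later disengagement (reverse causation) rather than the
other way round.

Because cohort MRI data of this kind are not publicly deposited, the
package ships a synthetic-data module that generates cohorts, ordinal
scale items, region volumes and 3-D map stacks with *known* parameters,
so every downstream stage can be tested, calibrated, and exercised end
to end.

## Cohort preparation

**Exclusion cascade.** Subjects are removed in two ordered stages:
failed MRI quality review first, then missing exposure measurement.  A
subject flagged for both reasons is counted once, at the quality stage —
this sequential convention makes the stage counts partition the
removals and the cascade idempotent.  On the reference configuration
(362 enrolled, 9 quality failures, 5 disjoint missing scores) the
counts are 362 → 353 → 348.

**Factor-based scoring.** The engagement score is a deterministic
one-factor score over 8 ordinal items: items are standardized, loadings
estimated by iterated principal-axis factoring of the Pearson
correlation matrix (communalities initialized at squared multiple
correlations and updated from the leading eigenpair until the maximum
change falls below 1e-9), and the score is the loading-weighted sum of
standardized items, centered at zero.  The loading sign is fixed so
higher scores mean more engagement.  We deliberately use this simple
estimator rather than a full categorical confirmatory factor model: the
downstream regressions need only a monotone, deterministic factor-based
score, and the principal-axis route has no tuning parameters, no
estimation stochasticity, and degrades gracefully (items with zero
variance are dropped with a warning; more than four degenerate items
abort scoring).  Subjects missing any item receive `NA` and fall to the
exclusion cascade.

**Design matrix.** All models share one right-hand side: intercept, age
centered at the sample mean, four education indicators (reference:
high school plus trade school), minority-race indicator, intracranial
volume (ICV, cc), hypertension, diabetes, a non-right-handedness
indicator, and control-status indicator — 12 columns.  Handedness
coding is binary right/non-right, the simplest rank-safe choice.
Indicators for category levels absent from a given sample are dropped
with a warning so the matrix always has full column rank; the rank is
verified by QR decomposition.  The exposure is *not* part of the shared
design; each model appends its own focal column, so the residual
degrees of freedom of every model are `n - 13` on the full design.

## ROI models

Each region is fit separately:
\[
V_r = X\gamma + \beta_r\, s + \epsilon,\qquad \epsilon \sim N(0, \sigma^2 I),
\]
with \(X\) the shared design and \(s\) the engagement score.  We report
the raw slope \(b_r\) (cc per score unit), the classical SE, t, and
two-sided p at the residual df, and the standardized coefficient
\[
\beta^*_r = b_r \cdot \mathrm{SD}(s)/\mathrm{SD}(V_r),
\]
using the *marginal* standard deviations of the focal predictor and the
outcome.  With covariates in the model this convention does not bound
\(|\beta^*|\) by 1, but it is scale-equivariant (rescaling a region's
volumes leaves \(\beta^*\), t and p unchanged) and is the convention
under which the synthetic generator's configured effects are recovered.
No multiple-comparison adjustment is applied across the 20 regions —
they are strongly dependent (several are unions of others) — so raw SEs
and p-values are reported and flagged at p ≤ 0.05.

Effect modification is tested by adding exposure-by-modifier
cross-product terms and comparing nested models with a joint F test
(single-df Wald for scalar modifiers).  Recognized modifier blocks:
age, education (4 indicators jointly), race, cardiovascular risk
(hypertension and diabetes jointly), control status.

The reversed models swap the roles: engagement is the outcome,
\(\Delta V_r = V_r^{(2)} - V_r^{(1)}\) the focal predictor, and
\(\beta^* = b \cdot \mathrm{SD}(\Delta V_r)/\mathrm{SD}(s)\).

All fits go through `stats::lm` on explicit numeric matrices; the test
suite verifies every reported number against an independent
normal-equations oracle (`(X'X)^{-1}X'y` with classical SEs) to 1e-8
relative tolerance, and verifies null-case p-value uniformity by
Kolmogorov–Smirnov over 500 simulated datasets.

## Voxel-wise GLM and cluster extraction

The voxel model is the same regression applied at every voxel of the
map stack, implemented as one shared QR projection applied across the
subject-by-voxel matrix — algebraically identical to per-voxel OLS but
hundreds of times faster.  The default analysis mask keeps voxels with
nonzero variance across subjects.  Two degeneracies are handled rather
than failed: zero-variance voxels get t = 0 (and are counted), and
perfectly fit voxels (zero residual, nonzero coefficient) get a signed
sentinel t of 1e6 with a warning.

The default voxel threshold is t > 3.11, the one-sided p = 0.001
critical value at the reference design's residual df (348 − 13 = 335;
`qt(0.999, 335)` = 3.115).  The contrast is one-sided positive: the
scientific hypothesis is that higher engagement goes with *larger*
volumes.  Suprathreshold voxels are grouped into connected components
under 26-neighbor connectivity by default (6 and 18 available); the
labeling is implemented as an edge list over neighbor offsets plus
graph components, and the test suite checks it against an exhaustive
breadth-first flood fill on random 16³ grids under all three
connectivities.  Components with fewer than 100 voxels (configurable)
are not reported.  Cluster centroids are reported in mm through the
stack's affine (0-based voxel convention).

## Max-cluster-size permutation inference

To control family-wise error across the map, each reported cluster is
referred to the permutation distribution of the *largest*
suprathreshold component: for each of 250 repetitions (default), the
images are permuted across subjects while the covariate and exposure
data stay fixed, the voxel GLM is refit, and the maximum component size
is recorded.  The cluster p-value is the plain proportion of
repetitions whose maximum is at least the observed size — no +1
smoothing of numerator or denominator, so p = 0 is representable and
p-values are multiples of 1/250.  Three deliberate choices:

- **Permutation scheme.** Raw images are permuted against the full
  fixed design (not residual-based schemes such as Freedman–Lane).
  When nuisance covariates truly affect the maps, this scheme is
  *conservative*: permutation moves covariate-explained variance into
  the null residuals, inflating null t-statistics.  We verified this
  directly — with covariate-driven global scaling of the maps switched
  on, the measured family-wise error at nominal 0.05 drops to 0.
- **Minimum size applies to reported clusters only.** The null maxima
  are never size-filtered; filtering the null would shrink null maxima
  and be anti-conservative.
- **Monotonicity.** For a fixed null the p-value is non-increasing in
  cluster size, so larger clusters always get smaller-or-equal p.

### Calibration substrate

The family-wise error calibration in the test suite runs 200 null
datasets at a desk-scale configuration (8×8×8 grid, n = 60, 100
permutations, unsmoothed noise).  Two substrate choices matter and are
worth recording:

- The null maps are generated with covariate coupling switched off, so
  images are exchangeable across subjects — the hypothesis the
  permutation test actually tests.  (With coupling on, the scheme is
  conservative by design; see above.)
- The calibration threshold is `qt(0.85, df)` rather than 3.11.  On a
  512-voxel grid, t > 3.11 leaves under one suprathreshold voxel per
  map, and any occupancy below the ~10% site-percolation point of the
  26-neighbor lattice makes max-cluster sizes heavily tied small
  integers, which renders the discrete proportion p-value conservative
  (measured FWER 0.02–0.03 at 5% occupancy).  At 15% occupancy the
  statistic is effectively continuous and the measured FWER is 0.045,
  within two Monte-Carlo SEs of the nominal 0.05.

## The synthetic-data generator

The generator's defaults are the reference study conditions: n = 348;
age ~ N(65.2, 7.9²) years; 90.5% white/non-Hispanic; 51.7%
hypertensive; 15.5% diabetic; 12.4% population-based controls; five
education categories at (48.0, 7.2, 25.9, 16.1, 2.9)% with high school
plus trade school the mode and reference; ICV ~ N(1450, 120²) cc; a
latent engagement score with SD 0.33; eight ordinal items with loadings
0.7; and the 20-region volume inventory with published mean volumes
(total brain 1137.96 cc, total GM 534.14 cc, …) and standardized
engagement effects defaulting to the published values (total GM 0.072,
corpus callosum 0.127, near-null WM effects).  Where the study gives no
generative value we chose once: the region coefficient of variation is
0.088 (the observed total-brain SD/mean), covariate couplings are
proportional to each region's mean with signs matching the descriptive
contrasts (older, hypertensive, diabetic, control ⇒ smaller volumes;
larger ICV ⇒ larger volumes), and the five-year change averages −1.25%
of the region mean (SD 2%) with zero engagement coupling by default —
the null temporal-reversal condition.

Useful structural properties, by construction:

- **Determinism.** Identical config + seed give bit-identical outputs;
  each generated object draws from its own substream of the root seed,
  so regenerating one object never shifts another.
- **Effect calibration.** The region noise SD is set so the marginal
  volume SD equals `roi_cv × mean`; the configured `roi_effects` are
  then exactly the standardized coefficients the forward models
  recover in expectation (verified: mean recovered \(\beta^*\) over
  100–200 replicates at n = 2000 within Monte-Carlo error of the
  configured 0.072).
- **Ordinal items.** A graded-response scheme: propensity =
  loading × standardized latent + unique noise, cut at equally spaced
  thresholds spanning ±2 (the item means and SDs give only ranges, so
  equal spacing is the neutral choice).  The weekly contact item has 8
  levels, the monthly items 5.
- **Voxel maps.** Smooth shared baseline (level 100, arbitrary map
  units) + covariate-driven per-subject global scaling + spherical
  effect blobs (amplitude × standardized engagement inside the
  support) + Gaussian noise smoothed at FWHM 2 voxels and rescaled to
  unit marginal variance, so blob amplitudes read directly in noise-SD
  units.  Default grid 32³ at 2 mm isotropic.

What the generator does **not** emulate: MRI physics, segmentation or
registration error, spatial autocorrelation structure of real
tissue-density maps beyond a single smoothing kernel, lesions, and any
intensity scale of real normalized-space maps (those are unpublished).
Passing tests therefore demonstrate the *statistical machinery* —
estimator correctness, calibration, error control — not fidelity to any
particular scanner or preprocessing pipeline.

## Numerical choices and degenerate inputs

- OLS via QR (`stats::lm`); singular designs raise an error naming the
  collinear columns rather than silently aliasing.
- Factor scoring: convergence tolerance 1e-9, max 500 iterations,
  communalities clipped to [0.05, 0.995]; singular correlation
  matrices fall back to max-absolute-correlation starting values.
- `extract_clusters` accepts an infinite threshold (empty set), and an
  empty mask yields an empty cluster set, not an error.
- Permutation seeds are explicit everywhere; the same seed reproduces
  the identical null distribution.
- Education probabilities are renormalized when they sum to within 2%
  of 1 (published percentage tables rarely sum exactly).

## Problem sizes in the shipped tests

The suite favors many small, fast checks: oracle comparisons at n = 40
on 6³ grids; labeling oracle on 16³ grids; p-uniformity and t-nullity
over 500 simulated datasets at 8³; effect recovery over 200 replicates
at n = 2000; family-wise error over 200 datasets at 8³ with 100
permutations; end-to-end blob recovery at 16³.  These sizes give
Monte-Carlo error small enough for the stated bands while keeping the
full suite in a few minutes on one core.

## Known limitations

- The permutation scheme is exact only under exchangeability of the
  images; with strong nuisance effects it is conservative (never
  anti-conservative in our measurements).
- \(\beta^*\) uses marginal SDs; conventions based on partial SDs
  would give different magnitudes.  The choice is documented, not
  data-derived.
- The factor score is a one-factor principal-axis approximation, not a
  categorical CFA; it is deterministic and monotone but its loadings
  will differ from weighted-least-squares CFA estimates.
- Cluster inference uses size only; cluster-mass and TFCE variants are
  out of scope.
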