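---
title: "Methods: causal structural covariance networks on pseudo time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal structural covariance networks on pseudo time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cascnr)
```

## The model

Voxel-based morphometry compares modulated gray-matter volume (GMV) maps
across subjects voxel by voxel. cascnr implements three analyses on such
maps, all driven by one configuration object:

1. **Overall comparison.** Patients vs controls, per voxel, by ordinary
   least squares on the design `[1, group, age_c, sex_c, tiv_c]` with a
   t contrast on the group column. Group is coded patient = 1 / control = 0
   and nuisance covariates are mean-centred, so the group coefficient is the
   adjusted group difference. Degrees of freedom use the design's rank, not
   its column count, so a constant covariate that gets dropped (with a
   warning) does not distort inference.

2. **Stage-specific comparisons.** Patients are split by illness duration —
   either at the patient median (a patient exactly at the median falls in
   the later stage) or at fixed boundaries (6, 11) years with an inclusive
   middle interval — and the overall comparison is repeated within each
   stage together with its matched controls.

3. **Seed-based CaSCN.** Patients are sorted by ascending illness duration
   into a pseudo time series; the mean GMV in a seed sphere gives the
   series `X_t`; every voxel's series `Y_t` is regressed on the lagged model

   `Y_t = sum_k A_k X_{t-k} + sum_k B_k Y_{t-k} + C Z_t + c + e_t`

   over the usable rows `t = p+1..n`. The reported signed-path coefficient
   is `A_1` (the per-lag cross coefficients are summed when p > 1). The
   mirrored equation, with the voxel's past predicting the seed's present,
   is available as `direction = "reverse"` (its cross coefficient is
   `B'_1`), but the forward direction is the default and the only one the
   standard analysis interprets.

The coefficient map is z-scored and both analyses end in
Gaussian-random-field (GRF) cluster correction at voxel p < 0.001 (one-sided
per sign branch) and cluster p < 0.01.

## Why a signed coefficient, and which z

A classical Granger statistic (an F or log variance ratio) is unsigned, yet
the interpretation the method trades on — *same* or *opposite* direction of
change in the target after change in the seed — requires a sign. The
package therefore reports the raw lagged regression coefficient. Two
z-scorings are implemented because the conventional toolchains do not
document theirs precisely:

* `spatial` (default): `z = (A - mean(A)) / sd(A)` over in-mask voxels.
  This asks "where is this voxel in the spatial distribution of
  coefficients", which is the reading consistent with thresholding a
  z-scored coefficient map as if it were a unit-Gaussian field.
* `wald`: `z = A / SE(A)` per voxel, the regression-internal alternative.

The choice is recorded in the map's provenance string.

## Model order

The model order defaults to p = 1. With roughly 80 ordered subjects there
is little information to support longer lags, the planted-effect generator
(below) defines its ground truth at lag 1, and a first-order model keeps
the "one step after" interpretation sharp. `gc_order` in the configuration
raises it; the per-lag cross coefficients are then summed into the map.

## Pseudo-time details that matter

* Ordering ties are broken by ascending subject id — deterministic, so
  reruns are identical.
* The duration-interval covariate is the first difference of the sorted
  durations with a leading 0 (the first patient has no predecessor). It
  absorbs the uneven spacing of the pseudo time axis.
* Covariates are mean-centred over the usable rows only (rows `p+1..n`),
  matching the rows the regression actually sees.
* Controls never enter the pseudo time series; they have no duration by
  contract (`duration` must be `NA` for controls, and loading fails
  otherwise).

## The phantom generator

`simulate_phantom()` produces the cohorts everything is tested on. The
baseline "head" is an ellipsoid of GM density 0.6 filling ~60% of the grid,
softened at 2 voxels FWHM, on a grid centred on MNI (0,0,0). Demographics
default to a realistic diabetic cohort: 81 patients and 48 controls, age
54.15 ± 9.26 y, duration 9.24 ± 6.61 y truncated below at 0.1 (inverse-CDF
sampling), 51/81 male. No TIV distribution accompanies those figures, so
TIV is drawn at 1.45e6 ± 1.3e5 mm³, a typical adult range; TIV acts only
as a nuisance covariate, so its scale is immaterial to the planted effects.

The planted structure mirrors exactly what the analysis is built to detect.
Patients are ranked by duration; the seed sphere loses
`seed_slope = 0.005` GMV units per duration year; the follower sphere of
the rank-r patient moves by `lag_coeff * (S[r-1] - 0.6)`, where `S[r-1]`
is the *realised* (noisy, smoothed) seed mean of the previous-ranked
patient — so the lag-1 dependency holds in the generated data themselves,
not just in expectation, and `simulate -> analyse` recovers
`A1 ≈ lag_coeff` by construction. Age (−0.002/y) and TIV (2e-8/mm³)
nuisance slopes apply globally (the follower sphere carries the lag term
only, keeping its construction identity exact); i.i.d. voxel noise
(sd 0.02) is added and each volume smoothed at 6 mm FWHM, the conventional
VBM kernel. With noise 0 and smoothing 0 the construction is exact, which
the tests assert literally.

Defaults (24×28×24 at 3 mm, radii 9 mm) keep a full pipeline run under a
few seconds on one CPU. What the phantom does *not* emulate: cortical
folding, partial-volume effects, spatially varying noise, registration
error. Passing tests therefore demonstrate the statistical machinery, not
robustness to real-MRI artefacts.

## Masking

The "optimal threshold" analysis mask is Otsu's method on the grand-mean
GMV image: a 256-bin histogram over the positive values, threshold at the
bin edge maximising between-class variance, mask = mean > threshold. It is
deterministic and parameter-free, excludes non-GM background as intended,
and is checked against an exhaustive-search oracle. Masks are recomputed
per analysis set (e.g. per stage subgroup), and the threshold used is
attached to the mask object. Whether GMV maps should be masked before or
after smoothing is left to the caller: masking here is applied at analysis
time only.

## Smoothing

Separable Gaussian convolution, σ = FWHM/(2√(2 ln 2)) per axis in mm
converted to voxels, implemented as banded matrix products. The convolution
is zero-padded with the kernel normalised to unit mass, so sums are
conserved away from the boundary (asserted in tests away from edges) and
mass leaks at the grid edge — the simplest convention that is exactly
reproducible. FWHM 0 is the identity.

## Smoothness estimation and GRF cluster inference

Residual images are standardised voxelwise; for each axis the ratio of the
squared spatial first difference to the field variance estimates
`2(1 - rho(h))` under a Gaussian autocorrelation, which inverts exactly to
a per-axis FWHM (the exact inversion, rather than the small-h expansion,
keeps the estimate honest on 3 mm grids). Per-image ratios are averaged
before inversion; FWHM is floored at half a voxel (logged) so resel counts
cannot blow up on near-white residuals. For t maps the residuals are the
GLM residuals; for the CaSCN map, the GC regression residuals.

Cluster p-values use the stationary-field results: expected cluster count
`E[m] = resels × (4 ln 2)^{3/2} (2π)^{-2} (u² − 1) e^{−u²/2}`, expected
suprathreshold volume `E[N] = V × Φ(−u)`, extent tail
`P(n ≥ k) = exp(−β k^{2/3})` with `β = (Γ(5/2) E[m]/E[N])^{2/3}`, and
`p = 1 − exp(−E[m] P(n ≥ k))`. Thresholds at or below u = 1 make the EC
density non-positive; the p-value is then reported as 1 rather than
extrapolated. Two-sided analyses run as two one-sided branches at the
stated voxel p each, mirroring separate reporting of atrophy and increase.
Non-stationarity is out of scope; the permutation oracle
(`permutation_cluster_null()`, permuting group labels or the pseudo-time
ordering) is the arbiter of the approximation, and the suite asserts
factor-of-2 agreement of critical extents at 4, 6 and 8 mm smoothness.

Cluster connectivity defaults to 26 (faces + edges + corners), the common
choice in this toolchain family; 6 and 18 are available and recorded.
Whether GRF is applied to t or z maps is likewise configurable: t maps are
thresholded at the t quantile with the equivalent z threshold in the GRF
formulas.

## Control allocation to stages

The stage analyses need control subgroups, but no allocation rule
accompanies the subgroup demographics a report typically prints. The
package's convention: capacities proportional to patient stage sizes
(largest-remainder rounding), then greedy assignment of controls to the
stage with the nearest patient mean age, in increasing distance order.
Deterministic, age-balancing, and always reported in the returned
`stage_split` object — reports print the allocation actually used.

## Numerical choices

* OLS via one QR decomposition shared across voxels; the GC model uses a
  Frisch–Waugh–Lovell split (shared block: intercept, seed lag,
  covariates; per-voxel block: the voxel's own lag) solved in closed form
  across all voxels, matching a per-voxel normal-equations solve to 1e-10.
* Rank-deficient voxel designs (constant voxels) yield non-finite
  coefficients and are excluded from maps and smoothness estimation, never
  silently zeroed.
* Affine equality tolerance for "same grid" is 1e-4 mm: serialization
  noise passes, real misregistration does not.
* All randomness flows through explicit integer seeds; `with_seed`
  restores the caller's RNG state, and rerunning any configured pipeline
  reproduces cluster tables byte for byte.

## Problem sizes used in the checks

The test suite exercises the headline properties at full scale: 100 random
GC instances against the normal-equations oracle; null calibration at
n = 80 with 2000 voxels; 20 + 20 phantom pipelines for planted-follower
recovery (Dice ≥ 0.3 against the planted sphere); 200 null phantoms
(20 + 20 subjects each) for the family-wise error bound; 2000-permutation
oracles at 4/6/8 mm; 20 replicate residual sets (20 images, 40³ at 1.5 mm)
for smoothness recovery. The permutation-uniformity property runs on
10×10×10 grids with 16 subjects and 60 permutations per replicate, sizes
chosen so the whole suite stays comfortably inside a coffee break; the
acceptance script uses 10 + 10 pipeline runs and 100 null replicates for
the same properties.

## Known limitations

* GRF cluster inference is approximate on small, coarse grids; the FWER
  property is asserted as a bound (≤ 0.05), not an equality, and the
  permutation oracle is the reference.
* The pseudo time series is an ordering of a cross-section, not a
  longitudinal observation; a "causal" coefficient here means lagged
  covariation along the duration axis, nothing stronger.
* Anatomical labelling is deliberately absent: outputs report MNI
  coordinates only, avoiding any atlas dependency.
* Only NIfTI-1 volumes on a common grid are consumed; registration,
  segmentation and modulation happen upstream.
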