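---
title: "Perfusion-diffusion habitat imaging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion-diffusion habitat imaging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatr)
```

## The problem

Rim-enhancing brain tumors such as glioblastoma are heterogeneous: inside
the contrast-enhancing (CE) lesion, regions with insufficient perfusion can
develop an acidic, treatment-resistant microenvironment. `habitatr`
quantifies that heterogeneity from routinely acquired multiparametric MRI.
Two *low-perfusion compartments* are delineated by intersecting thresholded
perfusion (rCBV) and diffusion (ADC) maps, characterized metabolically with
2D MR spectroscopic imaging (MRSI), related to a diffusion-tensor measure
of invasiveness, and carried into survival models.

All inputs are assumed co-registered onto one voxel grid; the package
checks grids (`check_grid_compatibility()`) and refuses mismatches rather
than resampling, because resampling choices upstream (interpolation,
target space) belong to the registration step, not the analysis.

## Habitat segmentation

For each subject:

1. **Normalization.** ADC and rCBV maps are divided by the arithmetic mean
   of their values inside a contralateral normal-appearing white matter
   (NAWM) mask, giving dimensionless maps with NAWM mean exactly 1
   (`normalize_by_nawm()`). The plain arithmetic mean is used; no trimming.
   Normalization is a positive scaling, so it never changes which voxels a
   quartile threshold selects — it standardizes the reported threshold
   values across subjects.
2. **Pooled quartiles.** Voxel values are pooled *within the CE ROI only*
   and the 25th/75th percentiles computed (`pooled_quartiles()`). Both the
   rCBV and the ADC thresholds are pooled over CE: the alternative of
   taking ADC quartiles over the whole map would let remote tissue shift
   the tumor thresholds. Quantiles use the linear-interpolation definition
   (`stats::quantile` type 7, the common scientific-software default);
   the type is configurable.
3. **Thresholding.** `rCBV_L` is the lowest rCBV quartile within CE (low
   perfusion); `ADC_L` and `ADC_H` the lowest and highest ADC quartiles
   (restricted and elevated diffusivity). Thresholds are *per subject*:
   each lesion is split against its own intensity distribution, which is
   robust to cross-subject scaling differences that survive NAWM
   normalization. Low masks use `<=` and high masks `>=`, so voxels tied
   exactly at a threshold are included; with heavy ties (e.g. a constant
   map) this over-selects, so tie counts are recorded in the thresholds
   table of every result and surfaced in subject reports.
4. **Intersection.** The compartments are `ADC_L-rCBV_L = ADC_L ∩ rCBV_L`
   (low perfusion with restricted diffusion — the high-cellularity,
   presumably hypoxic habitat) and `ADC_H-rCBV_L = ADC_H ∩ rCBV_L` (low
   perfusion with elevated diffusivity — microstructure loss). Remaining
   CE voxels form the contrast-enhancing control (CEC). By construction
   the three masks partition CE exactly, and the two compartments are
   disjoint whenever the ADC values in CE are non-constant (then
   `q1 < q3`).
5. **Volumetrics.** Absolute volumes in cm³ (`voxel count × voxel volume`)
   and proportional volumes as a percentage of the CE volume.

CE masks smaller than 64 voxels (configurable) are flagged — quartiles of
a handful of voxels are unstable — but volumes are still computed.

## MRSI aggregation across resolutions

MRSI is acquired roughly 10× coarser in-plane than the image grid, so a
compartment rarely coincides with spectroscopic voxels. The package models
each spectroscopic voxel as an axis-aligned block of image voxels
(`mrsi_grid()`), then:

- keeps only spectroscopic voxels whose block lies *completely* inside the
  tumor ROI and which pass spectral quality (a pass/fail flag in the
  input, or a Cramér–Rao-style relative-SD threshold, default 20%);
- weights each remaining voxel by the fraction of its block covered by
  the compartment;
- renormalizes weights to sum to 1 and reports the weighted mean of the
  metabolite ratio (`weighted_metabolite()`).

The renormalization matters: a raw coverage-weighted *sum* would scale
with compartment size, which is meaningless for a concentration ratio; as
a weighted mean the value always lies in the convex hull of the
contributing ratios, and equals the plain mean when coverages are equal.
Subjects with no eligible spectroscopic voxel get an explicit
missing-value record and drop out of metabolite analyses only — mirroring
the common situation where only a subset of a cohort has usable MRSI.
In-plane interpolation of the spectroscopic data is deliberately not
modeled; coverage is counted at image-grid resolution, so the weighted
value is invariant to uniform upsampling of the image grid.

## Diffusion-tensor invasive phenotypes

From the tensor eigenvalues, with MD = (λ₁+λ₂+λ₃)/3:

- isotropic component `p = √3 · MD`,
- anisotropic component `q = √((λ₁−MD)² + (λ₂−MD)² + (λ₃−MD)²)`.

`q` is permutation-invariant and zero exactly for isotropic tensors; for a
cylindrically symmetric tensor (a, b, b) it reduces to `√(2/3)·|a−b|`.
Negative eigenvalues (noise) are clamped to zero with a warning and a
count; non-finite voxels propagate as `NA` and are counted.

Abnormality masks for p and q are inputs when available; otherwise a
configurable z-score rule is applied (value > NAWM mean + 2 SD), restricted
to the FLAIR∪CE envelope when a FLAIR mask is supplied — without that
restriction the ~2% of normal voxels exceeding the threshold by chance
would dominate a maximum-distance statistic. The *margin* of each
abnormality is the maximum Euclidean distance (mm) of its voxels beyond
the CE surface, computed against CE boundary voxels, so it is accurate to
roughly one voxel. The phenotype rule — *minimal* if both margins < 10 mm,
*diffuse* if the p margin exceeds the q margin by > 10 mm, *localized*
otherwise — is a provisional package default: the original criteria live
in prior work and are not restated here, so both thresholds are
configurable and externally assigned labels override the rule.

## Cohort statistics

Group comparisons use Welch's t-test, Wilcoxon rank-sum or Kruskal–Wallis
as appropriate, with Benjamini–Hochberg adjustment within each comparison
family; correlations are Spearman's rank.

Continuous imaging and metabolite variables are dichotomized for
Kaplan–Meier analysis at the cutpoint maximizing the standardized
two-sample log-rank statistic over all splits leaving at least a
`minprop` (default 0.1) fraction of subjects on each side — the
maximally-selected rank statistic construction, computed from log-rank
(Nelson–Aalen) scores. Two caveats are built into the interface:

- the reported naive log-rank p-value after dichotomization is
  anti-conservative, because the split was chosen to maximize exactly that
  statistic; a permutation-corrected p-value (`n_perm`) is available;
- the reported threshold is the midpoint between the optimal split value
  and the next distinct covariate value (the grouping is identical to
  reporting the left edge; the midpoint makes the "between the clusters"
  location explicit).

Cox models use the partial likelihood with Efron tie handling (the common
default; ties are frequent once times are recorded in whole days), Wald
95% confidence intervals, and AIC = −2 logPL + 2k. Stepwise selection is
greedy: forward starts from the null model and adds the single covariate
with the largest AIC decrease; backward starts from the full model and
drops likewise; both stop when no step lowers AIC, and both run on the
complete cases over *all* candidates so AICs are comparable across visited
models. Missing covariates (e.g. MGMT status) are handled by per-model
complete-case analysis with dropped-row counts recorded. Greedy search
can in principle miss the best-AIC subset; on four or fewer candidates the
test suite compares it against exhaustive search and requires agreement in
at least 95% of simulated cohorts, with the residual cases verified to be
genuine greedy-unreachable optima.

## What the synthetic generator emulates — and what it does not

`make_phantom()` builds a subject with known ground truth: an ellipsoidal
CE lesion (default radii 16×14×12 mm on a 70×70×48 grid at 1 mm
isotropic, ≈ 11 cm³) whose innermost 25% of voxels form the low-perfusion
core, split ~35/65 into restricted- and elevated-diffusivity subregions
(the elevated side larger, as observed in practice); a FLAIR envelope
6 mm beyond CE; a contralateral 10 mm NAWM sphere placed farthest from
the lesion; tensor eigenvalues with anisotropic white matter and
near-isotropic tumor/edema; and a one-slice MRSI slab of 10×10×1-voxel
blocks on the mid-lesion slice.

In the default *separated* mode, region intensities are truncated
Gaussians with disjoint supports (core rCBV strictly below rim rCBV;
restricted ADC < rim ADC < elevated ADC), so the planted core is exactly
the lowest pooled quartile and recovery must be near-perfect — this turns
the whole habitat pipeline into a testable fixture. The *overlapping*
mode drops truncation to exercise graceful degradation. Spectroscopic
ratios are planted as the coverage-weighted mixture of per-region means
(restricted core 1.2, elevated core 0.9, CEC 0.5, outside 0.25 for
Lac/Cr) plus Gaussian noise (SD 0.05), so the recoverable truth for a
compartment is the corresponding mixture expectation.

The phantom deliberately does **not** model MR physics (k-space noise,
partial volume beyond block averaging, chemical-shift displacement),
registration error, irregular lesion shapes, or spatial intensity
gradients. Passing the recovery checks therefore shows the *pipeline
arithmetic* is right — thresholds, intersections, weights, distances —
not that the biological compartments are identifiable in any given
clinical dataset.

`make_cohort()` draws clinical covariates mirroring a treated
glioblastoma cohort (n = 80 with survival data; age ≈ 59 ± 10; 75% male;
67% complete resection; 44% MGMT-methylated with a few missing; 6% IDH-1
mutant; log-normal lesion volumes) and exponential survival times with
hazard `h₀·exp(Σβx)` (baselines set to median OS ≈ 455 days and median
PFS ≈ 265 days). Censoring is independent exponential with the rate
chosen so the expected censored fraction equals the requested rate
(default 30%), which keeps the censoring non-informative. Planted β are
returned for recovery tests.

## Numerical choices

- Quantile definition: type 7; configurable (`quantile_type`).
- Threshold inclusivity: `<= q1` / `>= q3`; ties counted and reported.
- Dice of two empty masks: 1 (agreement on absence); configurable via
  `empty_value`.
- Masks are `uint8` in NIfTI files, logical arrays in memory; voxel size
  is carried by the sform affine (column norms) on write and read.
- Margins: brute-force Euclidean distance to CE boundary voxels, exact up
  to voxel discretization; no chamfer approximation.
- Weighted-metabolite weights: non-negative, renormalized, recorded per
  voxel in the result for auditability.
- Determinism: phantom and cohort generators consume a private RNG stream
  seeded from their spec and restore the caller's RNG state; subject and
  cohort reports contain no timestamps, so reruns are byte-identical, and
  every report carries a configuration hash.

## Problem sizes used by the property checks

The test suite and the acceptance script exercise: 100 random phantoms on
a 40×40×24 grid (partition invariant; grid size does not affect the
invariant), five full-size 70×70×48 phantoms (core recovery, quartile
counts), 50 phantoms for MRSI oracle agreement, 20 simulated cohorts of
50–500 subjects for cutpoint–oracle equality, 50 cohorts of n = 500 for
Cox recovery of a true HR 2 under 30% censoring, 1000 null simulations
for log-rank calibration, and 50 cohorts of n = 200 with four candidates
for stepwise-vs-exhaustive agreement. On the Cox recovery check it is
worth noting the arithmetic: 30% censoring leaves ≈ 350 events, so
se(log HR) ≈ √(4/350) ≈ 0.107 and the acceptance band [1.7, 2.35] is only
about ±1.5 standard errors wide — per-run coverage is therefore expected
near 87%, and the observed rate fluctuates around that value across
seeds.

## Known limitations

- The phenotype decision thresholds are provisional defaults, not
  validated criteria; prefer externally assigned labels where available.
- Per-subject quartile thresholds adapt to each lesion but make absolute
  comparisons of threshold values across subjects meaningless by design.
- The naive post-dichotomization log-rank p-value inflates type-I error;
  use the permutation option for confirmatory claims.
- MRSI coverage counting assumes axis-aligned spectroscopic blocks on the
  image grid; oblique slabs must be resampled upstream.
- No imputation: all missingness is complete-case per model.
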