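---
title: "Quantifying aneurysm morphology and testing for sex differences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aneurysm morphology and testing for sex differences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind each
stage, the tunable parameters and why their defaults are what they are, what
the synthetic-data generators do and do not emulate, and the numerical
choices a maintainer would otherwise have to reverse-engineer from the code.

## 1. The problem

Women carry a higher rupture risk of unruptured intracranial aneurysms than
men. Because larger and more irregular aneurysms are rupture-prone, a
cross-sectional comparison of 3D morphology between the sexes — adjusted
for age, hypertension, smoking, aneurysm size, location and imaging
modality — asks whether morphology can explain that excess risk. The
package implements the entire chain: binary segmentation mask → watertight
surface mesh → seven morphology parameters → transformed, standardized,
imputed regression analysis with pooled women-vs-men contrasts.

## 2. From mask to mesh

**Grid conventions.** A `voxel_mask` is a binary 3D array with spacing in
mm and an origin; world coordinates are `origin + index * spacing`
(voxel-center convention, 0-based indices).

**Harmonization.** `resample_mask()` interpolates the binary field
trilinearly and re-thresholds at 0.5. Grids are aligned voxel-as-cell
(sample positions `-0.5 + (j + 0.5) * ratio` in input-index units), which
removes the half-voxel boundary bias a center-aligned scheme produces; the
measured voxel-count volume change for a 10 mm sphere resampled 1.0 → 0.5 mm
is a few tenths of a percent. The default target spacing is 0.25 mm
isotropic — finer than typical CTA/TOF-MRA voxels, so the shape features are
resolution-stable; it is a configuration parameter, not an estimate.

**Iso-surfacing.** `extract_mesh()` runs marching tetrahedra: each grid cell
is split into six tetrahedra around a fixed main diagonal, so face diagonals
agree between neighbouring cells and the triangulated 0.5-level surface is a
closed, consistently wound 2-manifold by construction (every edge shared by
exactly two faces; Euler characteristic 2 on genus-0 phantoms). This is the
same linear edge interpolation as classic marching cubes without the
ambiguous-case tables. Masks are padded with background before surfacing, so
foreground touching the grid boundary is handled by padding, never rejected.

**Anti-aliasing, not mesh smoothing.** Iso-surfacing a *raw* binary field
produces a surface whose area does not converge to the truth: for a sphere
at radius/spacing = 40 the area overshoots by about +9% (volume is fine).
The package therefore convolves the occupancy field with a small Gaussian
(`smooth_sigma`, default 1 voxel) before surfacing; the sphere's area error
drops to a fraction of a percent. The cost is edge rounding on shapes with
sharp creases: a voxelized cube loses roughly 1% of its area per 0.2 voxels
of sigma, an error that vanishes as voxels shrink. Since aneurysms are
smooth blobs, the curved-surface regime wins. No mesh-vertex smoothing is
ever applied; `smooth_sigma = 0` restores the raw behaviour.

## 3. Morphometry

* **Volume and area** come from the mesh (signed tetrahedra against the
  origin; triangle-area sum). Degenerate triangles contribute zero area.
* **Sphericity** `(36π V²)^{1/3}/A` equals 1 only for a ball.
* **Elongation and flatness** are `√(λ₂/λ₁)` and `√(λ₃/λ₁)` of the
  population covariance of foreground voxel centers (axis lengths
  `2√(5λ)`, exact for a uniform ellipsoid). They are computed from the
  voxel cloud rather than mesh vertices because vertex clouds over-weight
  high-curvature regions.
* **Principal curvatures** are estimated per vertex by fitting a quadric
  height field in the tangent frame of the outward vertex normal and taking
  the eigenvalues of the Monge-patch shape operator, with the sign fixed so
  convex regions are positive. The neighbourhood is a breadth-first walk
  over mesh edges gated at Euclidean radius `curvature_radius` (default
  12 × mean spacing). That radius is the one genuinely tunable constant of
  the morphometry: a 2-ring fit is far too noisy on iso-surface meshes
  (sphere shape-index median ≈ 0.4 instead of 1.0), while 12 voxel widths
  recovers sphere and cylinder curvatures to a few percent and the sphere
  criteria (`S = 1.00 ± 0.02`, `C = 0.100 ± 0.005 mm⁻¹` at r = 10 mm,
  0.25 mm spacing) with margin — the convergence tests in
  `test-morphometry.R` document the accuracy at three resolutions. On
  meshes beyond 20 000 vertices curvature is evaluated on an evenly spaced
  deterministic subsample; medians are unaffected.
* **Shape index and curvedness** use Koenderink's raw [−1, 1] convention
  with convex positive; whether the reference analyses used this or the
  rescaled [0, 1] variant is not documented, so the convention is kept
  explicit here (the ×100 display magnitudes are compatible with either).
  Umbilic points map to ±1 by the sign of the mean curvature; planar points
  (`κ₁ = κ₂ = 0`) are undefined and are excluded from the medians, which
  are otherwise unweighted over vertices ("each point on the mesh");
  area-weighting was considered and rejected as a default because the
  unweighted median is what the field reports.
* Records carry ×100 display copies of the five dimensionless/local
  parameters, matching the reporting convention of the cohort tables.

## 4. Voxel phantoms: the imaging-side stated world

Phantoms (`sphere`, `ellipsoid`, `capsule`, `sphere_with_blebs`) are
voxelized analytically — point-in-shape tests at voxel centers after an
optional rigid rotation — and every truth value is a closed form computed
independently of the morphometry code: sphere V/A/Ψ/S/C; ellipsoid V and
axis ratios (plus Thomsen's area approximation); capsule V/A and the axis
ratios from its analytic second moments; bleb phantoms carry their parent
sphere's values as reference bounds. Blebs are spherical caps centered on
the parent surface at seeded-random directions — the classic irregularity
feature. Features smaller than 4 voxels are rejected as under-resolved
rather than silently aliased.

Phantoms deliberately do **not** emulate parent vessels, necks, imaging
noise, or partial-volume intensity profiles: a green phantom test
establishes that the geometry pipeline measures shapes correctly, not that
segmentation of real angiography would be accurate.

## 5. The cohort simulator: the tabular stated world

`sim_params()` defaults encode the reference cohort's marginals: n = 326,
73% women; age 58 (12) / 61 (13) years; hypertension 53% / 68%; smoking
current/former/never 44/29/27% vs 38/39/23%; the five-location and
MRA/CTA distributions; log-normal size with medians 5.4 / 6.3 mm and
IQR-derived log-SDs; 45% / 31% multiple aneurysms; 2% missing smoking,
missing-at-random with a +0.8 log-odds for women (reproducing the observed
6-of-239 vs 1-of-87 imbalance).

Morphology is simulated directly on the analysis scales — a latent variable
per parameter with marginal SD near 1 — with configurable women-vs-men
effects in SD units (defaults are the reference univariable estimates,
e.g. −0.33 for log-volume) plus modest covariate effects so confounding
adjustment is exercised; latents are then mapped onto the raw scales using
the reference medians and IQRs. Two design points deserve emphasis:

* **The sex effect is the estimand.** For every parameter except volume the
  analysis adjusts for log-size, so the configured effect is exactly the
  conditional women-vs-men contrast. Volume's model is *not* size-adjusted
  (size and volume are the same construct), so its size contribution is
  centered per sex **and per aneurysm count** using the analytic mean of
  the maximum of k standard normals (0, 1/√π, 1.5/√π for k = 1, 2, 3).
  Without that centering, the sex differences in size and in multiplicity
  would leak into the volume contrast through largest-aneurysm selection
  and the configured effect would not be what the model estimates — the
  simulator's null would reject at ~13% instead of 5%.
* **Speed by construction.** Simulating on the analysis scales keeps a full
  cohort draw at a few milliseconds, so 500-replication recovery and
  1000-replication calibration runs stay inside desk-scale budgets; the
  end-to-end phantom-cohort route (masks → morphometry → statistics) is
  exercised separately at small n through the batch interface.

What a green simulator test establishes: the pipeline recovers configured
effects without systematic bias, with nominal type-I error and CI coverage,
under a correctly specified generator. It does not establish robustness to
model misspecification, measurement error in covariates, or informative
missingness — none of which the reference analysis addressed either.

## 6. The statistical engine

* **Transforms.** Volume: natural log. Elongation: Box-Cox with λ estimated
  once on the observed column by profile maximum likelihood over [−3, 3]
  (golden-section refinement) and then frozen, so all imputed data sets use
  the same transform. All outcomes are Z-standardized with moments computed
  once on the complete pre-imputation columns — morphology is complete by
  contract, only smoking is ever missing, so those moments are well-defined;
  whether the reference study standardized before or after imputation is
  unstated, and this choice is declared, not inferred.
* **Dichotomization** of the local parameters is at the sample median with
  values strictly above coded 1 ("above-median = 1" read strictly; ties go
  to 0), so the 1-group never exceeds 50%.
* **Models.** OLS for the standardized global parameters, maximum-likelihood
  logistic regression for the dichotomized local parameters, and exploratory
  continuous (linear) models for the local parameters. Men are the
  reference; the multivariable adjustment set is age, hypertension,
  smoking (ever vs never), log-size, location with PCom and posterior
  circulation collapsed, and modality; the volume model omits size. Wald
  intervals throughout (t with residual df for OLS, normal for logistic);
  profile likelihood is not used. Complete separation is reported as an
  error, not penalized away. Rank deficiency is reported with the aliased
  columns.
* **Imputation.** Chained equations with one incomplete variable reduce to
  repeated draws: per chain and sweep, the smoking model — nested binary
  logits (current vs not, former vs never), the sequential-logit analogue of
  polytomous regression — is refitted on a bootstrap resample of the
  complete rows (propagating parameter uncertainty) and categories are
  drawn for the missing rows; the final sweep is kept. Defaults 15
  imputations × 30 iterations. With zero missingness the m completed
  tables are identical to the input, so the imputation path reproduces the
  complete-data analysis exactly — a tested invariant.
* **Pooling.** Rubin's rules: pooled point = mean, `T = W̄ + (1 + 1/m)B`,
  CI from t with Barnard–Rubin degrees of freedom (classic Rubin df when
  the complete-data df is infinite; complete-data df when B = 0). The
  reference report does not state its pooled df; Barnard–Rubin is the
  mice default and is used here.
* **Power.** `required_sample_size()` evaluates the noncentral-F power of
  the overall model test with Cohen's noncentrality `λ = f²(u + v + 1)`,
  solves the continuous denominator df v by root search, and reports
  `u + v` rounded — the convention of the standard `pwr`-style calculators,
  which reproduces the published 307 for u = 8, f² = 0.05, α = 0.05,
  power = 0.80 (v\* ≈ 299.28). The alternative "smallest integer N with
  λ = f²N whose own power reaches the target" is available as
  `convention = "total-n"`; it gives 309. The discrepancy is a convention
  difference, not a numerical one, and both paths are tested against direct
  noncentral-F evaluation.
* **Sensitivity analyses.** (1) drop smoking from the adjustment set, full
  cohort; (2) keep smoking, complete cases only. With no missing values
  analysis 2 equals the main analysis exactly (tested).

## 7. Direction annotation

The instability coding — larger volume, lower sphericity/elongation/
flatness, lower shape index, higher curvedness are rupture-prone — is a
fixed lookup. A women-vs-men estimate whose 95% CI excludes the null is
labelled "more/less rupture-prone in women" accordingly; others are
"no difference". Significance means CI exclusion; no p-values are computed
or corrected (the reference analysis applied no multiplicity correction).

## 8. Degenerate inputs and numerical tolerances

Empty masks, non-positive spacings, constant columns, one-class outcomes,
rank-deficient designs, masks too thin for a 3D covariance, features under
4 voxels, and non-watertight meshes are all rejected with specific errors.
Sphericity may exceed 1 by discretization only within 1e-9. Shape-index
clamping to [−1, 1] guards arctangent rounding. Vertices with fewer than 8
usable neighbours are flagged invalid and excluded from medians; fewer than
50 valid vertices triggers an unreliability warning.

## 9. Known limitations

* The curvature scale depends on the neighbourhood radius; curvedness
  medians are therefore comparable *within* a harmonized pipeline but not
  across packages with different estimators — one reason the analysis
  standardizes and dichotomizes rather than interpreting raw magnitudes.
* The NIfTI reader handles single-file NIfTI-1 masks with orthogonal
  axes; oblique orientation matrices and NIfTI-2 are out of scope.
* The simulator draws covariates independently within sex (beyond the
  built-in sex differences); real cohorts have richer correlation
  structure.
* Cross-sectional only: nothing here estimates rupture risk or growth.
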