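---
title: "Quantifying subchondral trabecular bone across CT resolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subchondral trabecular bone across CT resolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabtex)
```

## The problem

Subchondral bone remodels under the altered loading of an osteoarthritic
knee, but the trabecular network (struts of ~0.1-0.3 mm, spaced ~0.5-1.5 mm)
cannot be segmented at the resolution of clinical whole-body CT (~0.25 mm
pixels, 0.5 mm slices). Grey-level *texture parameters* — statistics of the
calibrated voxel-value distribution that do not require a binarized network —
are a practical surrogate, but their values depend on the scanner's spatial
resolution and noise. Before a texture value measured in a patient CT can be
interpreted, one has to know *how* each parameter transforms between a
high-resolution reference (HR-pQCT, 82 µm isotropic voxels) and the clinical
geometry.

`trabtex` implements the full comparison machinery: a digital trabecular-bone
generator with a simulated imaging chain for both geometries, density
calibration, periosteal segmentation with automatic placement of the sixteen
knee analysis VOIs, rigid surface registration so that both modalities are
measured at identical anatomical locations, the five texture parameters, and
the cross-modality statistics (regression, Bland-Altman limits of agreement,
resolution-dependence ratios `D = TP_HR / TP_CT`, two-sample tests).

## The five texture parameters

All texture is computed on BMD-calibrated volumes (mg/cm³) inside a VOI mask.
Second-moment statistics use the population convention (divide by *n*)
throughout the package, so small-sample oracle tests are exact.

* **Entropy** (bits): Shannon entropy of the voxel-value histogram with a
  *fixed* bin width (default 25 mg/cm³) over a *fixed* range (default
  [-100, 1500) mg/cm³). A fixed binning is essential: a data-dependent
  binning would make entropy incomparable between modalities. Out-of-range
  values are clamped into the edge bins.
* **Global inhomogeneity** (mg/cm³): population SD of all VOI voxels.
* **Local inhomogeneity** (mg/cm³): mean, over voxels whose full cubic
  neighborhood (default 3³) lies inside the mask, of the neighborhood
  population SD. The radius is defined in voxels, *deliberately*: a physical
  structure spans fewer voxels on a coarser grid, and this voxel-scale
  definition is what makes the parameter resolution-dependent. A physical
  radius can be emulated by passing a different `radius` per modality.
* **Anisotropy** (dimensionless, [0, 1]): per interior voxel, the structure
  tensor averages outer products of central-difference gradients (gradients
  in physical units, so anisotropic grids are handled correctly) over the
  cubic neighborhood; local anisotropy is `1 - lambda_min / lambda_max`,
  defined as 0 when `lambda_max` is below tolerance (constant regions); the
  VOI value is the mean over interior voxels. This is a surrogate for the
  original study-line formula, which is not public; it is bounded, rotation
  aware, and reduces to the intuitive limits (0 for isotropic neighborhoods,
  1 for variation along a single direction).
* **Variogram slope** ((mg/cm³)²/mm): ordinary least-squares slope of the
  empirical semivariogram `gamma(h) = 0.5 mean[(v(x+h) - v(x))^2]` over
  axis-aligned in-mask pairs at the physical lags of 1-4 voxels per axis
  (pooled over axes; an anisotropic grid contributes distinct lags per
  axis). Lags without pairs are dropped with a warning; fewer than two
  usable lags is an error.

VOIs smaller than 27 voxels raise a per-VOI error rather than returning a
silently unstable value. `compute_all()` degrades per parameter: a VOI whose
shape cannot support a neighborhood statistic (e.g. a cortical shell thinner
than 3 voxels on the CT grid) reports `NA` for that parameter and keeps the
others.

## The digital phantom

`trabecular_params()` describes a jittered orthogonal rod lattice with plate
insertions. Square-section rods of width `trab_thickness` run along all
three axes on a cubic grid of pitch `trab_separation`; a fraction
`plate_fraction` of cells carries a solid transverse plate; each cell's
whole junction is displaced by one uniform random offset (fraction `jitter`
of the pitch), staggering rod segments at cell boundaries. Two design points
deserve explanation:

* **Per-cell displacement, not per-rod offsets.** Displacing the junction as
  a unit keeps the bone volume of every cell exactly equal, so the bone
  volume fraction of a generated model tracks the parameters deterministically
  and a monotone parameter sweep yields a strictly monotone volume-fraction
  ordering. Independent per-rod offsets would randomize the rod/plate overlap
  volumes and wash out small sweep steps.
* **Exact plate count.** Plate cells are chosen by ranking per-cell uniforms
  against a threshold that realizes exactly `round(plate_fraction * n_cells)`
  plates among the cells the volume samples, again removing binomial noise
  from the sweep.

A large-scale *heterogeneity field* (`heterogeneity`, default 0.25 fractional
SD with a 2 mm correlation length) modulates the bone-tissue density. Real
trabecular bone is not homogeneous at the millimeter scale — mineralization
and local remodeling vary regionally — and this low-frequency component is
precisely what survives clinical-CT blurring. Without it, the simulated CT
image of a periodic lattice is unrealistically flat: its global
inhomogeneity collapses to a few percent of the HR value and the entropy
comparison inverts. The pure two-valued lattice is recovered with
`heterogeneity = 0`.

Defaults (thickness 0.15 mm, separation 0.8 mm, plate fraction 0.5, bone
1000 mg/cm³ over 30 mg/cm³ marrow) describe plate-rich subchondral bone.
The default 40-model suite (`generate_model_suite()`) sweeps thickness
0.10 to 0.22 mm and separation 1.1 to 1.4 mm jointly upward — thickened,
more widely spaced trabeculae, the direction of reported osteoarthritic
remodeling, at dimensions typical of elderly donors.

`generate_knee_phantom()` assembles a distal-femur-like (or mirrored,
proximal-tibia-like) body from two condylar spheres and a capped shaft
cylinder, with a dense cortical shell (Euclidean-distance erosion), the
trabecular interior, and a soft-tissue background, and returns the geometry
needed for VOI placement (shaft axis, planar growth-plate approximation,
medial/lateral plane). The default phantom is a ~25 mm miniature, not an
anatomically sized knee: every analysis step sees realistic contrast and
geometry at a desk-scale memory budget.

## The imaging chain

`simulate_imaging()` maps a fine ground truth onto a scanner grid in three
steps, in this order:

1. **PSF blur**: separable Gaussian of FWHM `psf_fwhm` (presets: 0.13 mm for
   HR-pQCT; 0.45 mm for the medium and 0.30 mm for the sharp clinical-CT
   reconstruction kernel — the named kernels' MTFs are not public, so these
   are plausible widths at the scale of the voxel sizes, and configurable).
2. **Partial-volume resampling**: volume-weighted box averaging — every fine
   voxel contributes to the coarse voxels it intersects in proportion to the
   shared volume. This is the separable exact form of partial-volume
   averaging; it conserves mass (the identity on a matching grid, and the
   mean to machine precision when the coarse grid tiles the fine one) and,
   unlike nearest-bin assignment, is free of aliasing between the lattice
   period and the voxel ratio.
3. **Noise**: additive Gaussian field of marginal SD `noise_sd` (presets
   50 mg/cm³ for HR-pQCT, 10 mg/cm³ for CT — the protocols' stated 5x
   ratio). The field is *reconstruction-correlated*: white noise smoothed
   with the profile PSF and rescaled to the requested SD. Reconstructed CT
   noise is correlated over the kernel scale; a strictly white field would,
   for example, have an exactly flat semivariogram and no noise response in
   the variogram slope, contrary to how real acquisitions behave. With
   `psf_fwhm = 0` the noise is white.

The calibration module mirrors clinical practice: clinical-CT attenuation is
converted to BMD by ordinary least squares on an in-scan rod phantom
(`fit_phantom_calibration()`), the HR device applies an internal calibration,
and because the two devices' phantom materials differ, their BMD scales
disagree systematically; `fit_cross_device_correction()` regresses the
HR values on the CT values over the trabecular VOIs (cortical VOIs excluded)
and the fitted line maps CT BMD onto the HR scale, leaving HR unchanged.

## Segmentation, VOIs, registration

`segment_periosteal()` is a deliberately simple surrogate for a clinical
knee segmentation, adequate for the synthetic phantoms: fixed threshold
(default 300 mg/cm³), Euclidean-ball morphological closing, largest
6-connected component, cavity filling. `define_vois()` places the 8 per-bone
VOIs from the geometry: the cortical shell of stated thickness
(distance-transform erosion difference) and the trabecular compartment
between articular surface and growth-plate plane, cut along the shaft axis
into three equal-thickness slabs (S1 subchondral-epiphyseal, S2
mid-epiphyseal, S3 juxtaphyseal — the true clinical VOI offsets are not
public, so equal thirds is the declared, configurable surrogate), each split
medial/lateral. Names follow `bone.layer.side`.

`register_rigid()` aligns the two modalities' periosteal surfaces: the
metric is the mean squared signed Euclidean distance (computed on the moving
mask's padded distance map) over the fixed mask's boundary voxels, minimized
by quasi-Newton (BFGS) descent with angle/translation scaling over a
three-level coarsening schedule (factors 4, 2, 1). BFGS was chosen over the
classical regular-step gradient descent of registration toolkits because it
needs no step-schedule tuning and is deterministic here; the padded distance
map keeps the metric informative when a misaligned transform maps surface
points beyond the moving volume, which is what gives the optimizer its
capture range of several degrees and millimeters. The returned transform
maps fixed-domain physical coordinates into the moving domain, directly
usable by `transfer_vois()` (nearest-neighbor pull-back, layer disjointness
re-enforced). Registration quality is validated with `dice_ratio()` on the
finer grid after upsizing, the study-line convention.

## What a green test does (and does not) establish

The synthetic world reproduces: two-valued trabecular contrast with
realistic dimensions and large-scale heterogeneity, partial-volume and PSF
effects of the two geometries, correlated scanner noise at the stated 5x
ratio, systematic cross-device calibration offsets, and a repositioned
acquisition requiring registration. It does *not* emulate: real anatomy
(shapes are spheres and cylinders; the medial/lateral plane is supplied, not
detected), beam hardening and scatter, the actual OSTEO/HA phantom
chemistries, motion artifacts, or the proprietary segmentation and VOI
geometry of the clinical software. Agreement statistics obtained here
therefore validate the *machinery* and the *direction and rough magnitude*
of resolution effects, not patient-level absolute values.

The resolution-dependence suite (`suite_resolution_dependence()`) images the
default 40-model sweep at both geometries and summarizes `D = TP_HR / TP_CT`
per parameter (two-stage means, cortical VOIs excluded by construction). By
default it uses equal, low noise (10/10 mg/cm³) rather than the protocol
levels: the prior simulation work this comparison emulates assumed
lower-than-protocol HR noise (that assumption is the published explanation
for the local-inhomogeneity discrepancy between digital models and
cadavers), and at the protocol ratio the 5x HR noise dominates the
histogram-based parameters — with `noise = c(hr = 50, ct = 10)` the entropy
direction inverts. Under the defaults the suite reproduces the reported
pattern: entropy higher with CT (mean D ≈ 0.89), global inhomogeneity and
variogram slope higher with HR-pQCT, anisotropy the most nearly
resolution-independent of the four headline parameters (mean D within 10% of
1). The variogram-slope ratio is far larger than the reported one (~15 vs
~1.5): the short-lag semivariogram of a two-valued lattice at 82 µm sees
nearly full bone/marrow contrast while the clinical grid sees blurred
residuals, and no attempt was made to match the original study's
(non-public) lag set and fit range; only the direction is asserted.

Anisotropy's noise robustness holds where it is claimed for real
acquisitions — structured bone — and specifically where structural gradients
dominate: on a dense
subchondral-sclerosis-like lattice the VOI anisotropy changes ~2% between
zero noise and the HR-pQCT preset, while for sparse lattices with large pure
marrow compartments the noise-dominated marrow tensors raise the sensitivity
above 10%. On a strictly constant field anisotropy is exactly 0 by the
zero-tensor convention, so a "relative change under noise" is only
meaningful on structured fields.

## Numerical choices

* Coordinate convention: 0-based voxel indices, `physical = origin + index *
  spacing` (voxel centers); all operations, transforms and VOI definitions
  share it.
* Population SD everywhere (including Bland-Altman limits of agreement,
  `1.96 * SD` of the differences, and the SD across cases in the D summary).
* Rigid transforms: intrinsic rotations composed `Rz(gamma) Ry(beta)
  Rx(alpha)` about an explicit center; serialized to JSON with an axis-order
  tag.
* Eigenvalues of the 3x3 structure tensor use the closed-form trigonometric
  method (verified against `eigen()` to 1e-6 and better in tests).
* Degenerate inputs fail loudly: empty VOIs, sub-minimum VOIs, degenerate
  calibration fits, non-overlapping registration inits, zero-valued D
  denominators are all errors, not NA propagation — except inside
  `compute_all()`/`run_experiment()`, which log per-VOI failures and
  continue, mirroring a batch analysis over many cases.
* Every stochastic operation takes an explicit integer seed; suites derive
  per-model seeds by fixed offsets; `run_experiment()` is reproducible from
  its JSON-serializable config (TOML is not supported by the installed
  toolchain, so the config format is JSON).

## Known limitations

* The anisotropy formula, entropy binning, variogram lag set, VOI slab
  geometry and PSF widths are configurable surrogates for non-public
  originals; absolute texture values are not comparable to the clinical
  software's.
* The simplified segmentation assumes an isolated bright bone body on a dark
  background; it is not a clinical knee segmentation.
* The phantom's cortical shell must be thick enough to survive PSF blur at
  the CT geometry, and the soft-tissue margin must exceed the closing radius
  plus the blur; the defaults respect this, but aggressive down-scaling can
  open the segmented shell and leave the interior unfilled.
* Desk-scale resolutions (ground truth at 0.02-0.03 mm instead of a true
  micro-CT 0.02 mm everywhere, miniature phantoms) trade accuracy limits for
  runtime; where a property is resolution-sensitive (strict volume-fraction
  monotonicity of the 40-model sweep) it is asserted at the native scale.
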