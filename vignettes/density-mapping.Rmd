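---
title: "Mapping bacterial colonization of the rhizosphere pore space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bacterial colonization of the rhizosphere pore space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizokde)
```

## The problem

Soil-dwelling bacteria such as *Bacillus subtilis* colonize plant roots
through the labyrinth of pores between soil particles. Live confocal imaging
of roots growing in transparent (Nafion-based) soil produces time series of
2-D maximum-projection tiles in which a trainable pixel classifier
distinguishes five classes: soil particle, pore space, mobile bacteria (MB),
biofilm on the root (RB) and biofilm on soil particles (PB). The root itself
is traced manually. `rhizokde` takes over from there: it turns class
probability stacks into patch tables, attaches spatial covariates, estimates
where in the pore space bacterial fluorescence concentrates, converts
fluorescence to cell counts, and summarises colonization per root over time.
A seeded synthetic microcosm generator reproduces the structure of such a
dataset (12 roots, timepoints at 12/24/36/48 h, 2-6 tiles of 3.2 x 3.2 mm
per root at 6.21 um/px), so every stage is testable without any microscope
data.

## From images to patches

Pixels are labelled with their maximum-probability class; ties are broken in
the fixed order PARTICLE < PORE < MB < RB < PB. The traced root polygon
overrides classifier output inside its boundary (pixel-center, even-odd
rasterization). Each bacterial class mask is decomposed into compact patches
by flooding the negated Euclidean distance transform from its regional
maxima (minimum seed separation 3 px, flood tolerance 1 px); this is the
standard shape-based splitting of merged blobs, and regions always partition
the mask exactly. Each region `i` becomes a patch with area $A_i$ (pixel
count times pixel area), mean intensity $I_i$ (raw by default; a constant
background can be subtracted), and the unweighted centroid of its pixel
centers. Regions below 4 px are discarded as sub-resolution noise
(configurable).

Every patch carries the covariate vector $x_i = (d_p, d_r, d_a)$ evaluated
at its centroid:

* $d_p$ — Euclidean distance to the nearest particle pixel (0 on/inside a
  particle), from the distance transform of the particle-mask complement;
* $d_r$ — likewise for the root mask;
* $d_a$ — distance from the root tip, read as the cumulative arc length of
  the nearest vertex of the traced centreline resampled to one-pixel
  spacing. The centreline is ordered tip-first, so $d_a = 0$ at the tip.

Evaluating covariates at the centroid (one $x_i$ per patch) matches the
patch-level description of the data; per-pixel evaluation would re-weight
large patches by shape, which the patch-level estimator below already does
through $A_i$.

## The weighted Parzen-window density model

With $N$ patches, the estimated probability density of bacterial position in
covariate space is the fluorescence-weighted kernel estimate

$$\tilde p(x) = \frac{1}{M} \sum_{i=1}^{N} A_i I_i \, K(x - x_i;\, h_i),
\qquad M = \sum_{i=1}^{N} A_i I_i,$$

so regions with more frequent or brighter patches get proportionally more
mass, and $\tilde p$ integrates to 1 when no kernel overhangs the attainable
region. Because patches have finite support and only mean intensities are
recorded, the kernel is a top-hat (Parzen window): constant inside the
ellipsoid $\sum_j (u_j/h_j)^2 \le 1$ and zero outside, with constant

$$C = \frac{1}{V_n \prod_j h_j}, \qquad V_1 = 2,\; V_2 = \pi,\; V_3 = \tfrac{4\pi}{3},$$

the exact ellipsoid-volume normalization, so each kernel integrates to 1
(checked numerically to 1e-3 in the tests). The bandwidth is the patch
radius, $h_i = \sqrt{A_i/\pi}$, applied isotropically on every covariate
axis, and floored at one pixel-equivalent (6.21 um at the default
resolution) so zero-measure kernels cannot occur.

Fields are evaluated at the centers of a configurable grid (defaults:
$d_p, d_r \in [0, 500]$ um at 10 um bins; $d_a \in [0, 10]$ mm at 0.5 mm
bins). Kernels overhanging the attainable region (e.g. $d_p < 0$) are *not*
renormalized; the resulting integral deficit is reported in the field's
metadata (`glance()`), so a Riemann sum below 1 is visible rather than
silently corrected.

**Coverage condition.** A top-hat kernel evaluated at grid-cell centers
deposits no mass at all if its radius is smaller than the distance to the
nearest center. The bandwidth floor should therefore be at least half the
cell diagonal whenever bins are coarser than typical patch radii; the null
model applies this floor automatically, and analyses on the coarse `da`
axis should either use finer bins (50 um in the package's own tests) or
pass `h_min_um` accordingly.

The mean cell-density field is $\rho(x) = \tilde p(x)\,\bar Q$, where
$\bar Q$ is the average calibrated bacterial quantity per root (total
calibrated cells over all patches divided by the number of roots $R$).
Temporal structure is represented as one independent field per timepoint
over a shared grid, each normalized within its own timepoint, matching how
per-timepoint maps are usually presented; `M` per timepoint preserves the
absolute-fluorescence comparison across times.

### The null model

To judge whether bacteria prefer particular regions, the same estimator is
applied under the hypothesis that every pore-space pixel is equally likely
to be colonized: each support pixel becomes a pseudo-patch with unit
intensity and one-pixel area ($h$ = pixel radius, floored per the coverage
condition above). Seeded uniform subsampling of support pixels keeps this
tractable; on a full default tile the subsampled field differs from the
exhaustive one by less than 0.05 in L1 mass.

### Recovering planted placement scales

The generator plants MB centroids over pore pixels with weight
$\exp(-d_r/\lambda_r)\exp(-d_p/\lambda_p)$. What a density field shows is
that law *times availability* (how much pore area exists at each covariate
value), so scales are recovered by weighted least squares of
$\log(\tilde p_{\mathrm{model}}/\tilde p_{\mathrm{null}})$ on the covariate
axes jointly (`recover_placement_scales()`). The joint fit matters:
single-covariate marginals are biased (by roughly 40% in our conditions)
because $d_p$ and $d_r$ are correlated in the pore space — particles are
scarce immediately next to the root — while the joint fit recovers both
scales within a few percent at 500 patches.

## Calibration and per-root statistics

Total patch fluorescence maps to cell counts through a straight line fitted
by ordinary least squares on images where individual cells could be
counted; the bundled default is `intensity = 39 * cells + 331`. Inversion
clamps at zero below the intercept, which is treated as per-patch
background. From calibrated patches the package derives:

* **Colonization states** per root and timepoint — `NONE`, `MOBILE_ONLY`,
  `MOBILE_AND_BIOFILM`, plus `BIOFILM_ONLY` for completeness (cohort tables
  can collapse it into `MOBILE_AND_BIOFILM` for the classic three-category
  presentation);
* **Cell-density profiles** along the root: calibrated cells per mm of root
  per root, binned over $d_a$ (0.5 mm default bins); profiles always
  integrate back to total cells divided by $R$, and bins beyond every
  root's length are masked;
* **Biofilm-tip distances**: the minimum $d_a$ over RB patches per root and
  timepoint, with cohort mean and SD. Per-root-by-timepoint minima are the
  exported unit; per-image minima can be derived from the patch table.

The comparison of tip distances at the last timepoint against earlier ones
uses a two-sided Mann-Whitney U test (exact null when both groups have at
most 20 observations and no ties; normal approximation with continuity
correction otherwise). A rank test was chosen because group sizes are small
and there is no evidence for normality of minimum distances; Welch's
t-test is available behind `method = "welch"`. Exact p-values are verified
against full enumeration of group assignments in the tests.

## The synthetic microcosm generator

The generator emulates the *structure* of the imaging study, not bacterial
physiology. Per scene it draws:

* **Particles**: non-overlapping discs, diameters uniform in 250-1250 um,
  rejection-sampled to a target packing fraction of 0.35 (a realistic areal
  fraction for a granular monolayer projection that still leaves a
  connected pore network), with an attempt cap so unreachable targets
  produce a warning and the achieved fraction, never a hang. Disc shape is
  a deliberate simplification: particle shape enters no downstream formula.
* **Root**: a smooth mean-reverting random-walk centreline entering from
  the tile edge, width 250 um; the boundary polygon is the centreline
  offset by half-width and the mask is its rasterization under the same
  even-odd rule segmentation uses. Tile 1 contains the tip; later tiles
  carry a mature segment with arc length offset by the tiles before it.
* **Patches**: per class and timepoint, Poisson counts with planted
  temporal weights (MB peaking at 12-24 h: means 12, 12, 6, 4 per tile;
  RB/PB increasing: 2, 3, 5, 7 and 1, 3, 5, 7), log-normal areas
  (median 1500-3000 um^2) and cells-per-patch (median 150-400). MB
  centroids follow
  $\exp(-d_r/100\,\mu m)\,\exp(-d_p/100\,\mu m)$ over pore pixels, times
  an early near-tip factor $\exp(-d_a/1.5\,mm)$ at 12-24 h (uniform
  later); RB sits uniformly on the root-boundary ring at
  $d_a \ge 794$ um (the planted tip-exclusion distance); PB sits uniformly
  on particle perimeters within 100 um of the root. The patch-size and
  cells-per-patch distributions are free parameters of the generator —
  the imaging study they emulate reports no quantitative equivalents — and
  are documented here as such.
* **Rendering**: each patch is painted on the `n` nearest legal-support
  pixels (`n` = drawn area in pixels), so the painted area equals the
  drawn area exactly and the summed patch intensity equals
  `39 * cells + 331` exactly before noise; the stored ground truth
  (centroid, area, covariates) is recomputed from the painted region, which
  makes it exactly recoverable by the segmentation stage. Patches never
  overlap (one-pixel separation), so watershed recovery is unambiguous.
  Probability stacks are one-hot in the ground-truth labels with optional
  label-flip noise; intensity noise is additive Gaussian over a constant
  background (both default to zero: noise levels are study knobs, not
  estimates).

All randomness flows from one seed through named sub-streams (per scene,
per stage), so any stage can be regenerated independently and identical
(config, seed) pairs give bit-identical scenes.

What the generator does **not** emulate: optics (no PSF, no Z-structure —
scenes are already max-projections), motility or growth dynamics (temporal
structure is planted, not mechanistic), irregular particle shapes, tile
misalignment, classifier errors beyond uniform label flips. Passing
recovery tests therefore demonstrates that the estimators are correct and
well-calibrated on data of this structure, not that the classifier or
microscope behave ideally on real images.

## Numerical choices

* Coordinates are pixel-center based, in um everywhere downstream of I/O;
  a point on the far tile edge belongs to the last pixel.
* Argmax ties go to the first class in the fixed order (documented and
  deterministic). All five classes compete in the argmax; excluding pore
  space would only relabel pore-adjacent noise pixels.
* Accumulation order inside `estimate_density()` is sorted canonically, so
  permuting patch rows gives bit-identical fields despite floating-point
  addition.
* Empty structures yield infinite distances (`dp = Inf` with no particles);
  estimation refuses non-finite covariates rather than silently dropping
  mass, and the null model reports when no support pixel has finite
  covariates.
* The test suite and examples run on reduced problem sizes chosen for
  desk-scale iteration: one full default tile (515 x 515 px) as the shared
  fixture, a 2-root noiseless cohort for recovery checks, 500-10000
  planted patches for distribution-level checks, and 1.6 mm tiles for I/O
  and pipeline round-trips. The full 12-root default cohort runs in a few
  minutes.

## Limitations

* The estimator inherits the top-hat kernel's rim quadrature error: a
  single kernel's Riemann sum on a fine grid is accurate to ~1%, so only
  multi-patch fields should be read quantitatively near that precision.
* Boundary truncation is reported, not corrected; fields whose kernels
  overhang the attainable region integrate to less than 1 by design.
* Cell counts below the calibration intercept clamp to zero, so very dim
  patches contribute no cells even though they contribute fluorescence
  mass to $\tilde p$.
* `da` for a point is the arc length of the nearest centreline vertex, not
  the true geodesic to the tip; for strongly curved roots the two differ
  most far from the centreline.
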