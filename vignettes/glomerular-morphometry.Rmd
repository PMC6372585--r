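---
title: "Measuring the mesangium: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the mesangium: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomorph)
```

## The measurement problem

The glomerular mesangium is the matrix-and-cell compartment that supports
the capillary tuft of the kidney's filtration unit; its expansion tracks
the progression of diabetic kidney disease. The quantities of interest are
three-dimensional — mesangial volume (µm³) and the mesangial fractional
volume Vv(mes/glom) — but the raw data are two-dimensional: serial 1 µm
PAS-stained sections photographed under light microscopy, or single TEM
micrographs. `glomorph` implements the three routes from sections to
volumes and the statistical harness for comparing them on the same
glomeruli.

## The three estimators

**3D reconstruction (prism extrusion).** Each traced contour on section
`i` is extruded into a right prism over `z ∈ [i·t, (i+1)·t]`, where `t` is
the section thickness. With only a handful of serial sections no
interpolation between planes is defensible, and the resulting model is
deliberately cylinder-like; as the number of sections grows it converges
on the true shape (the test suite verifies monotone convergence on a
sliced sphere). The mesh volume is exactly `t · Σᵢ Aᵢ` — the Cavalieri
identity — and is computed independently via the divergence theorem on the
triangle mesh; the two routes must agree to 10⁻⁹ relative, which the tests
enforce on random stacks. Disjoint contours are extruded separately and
summed; nothing is merged across contours.

Two surface-area conventions exist because stacked prisms share internal
faces: `union_external` (default) counts lateral walls plus only the
exposed top/bottom cap area of the stacked union, while `component_sum`
counts every prism's caps in full. The convention in force is recorded on
the mesh. The union overlap between adjacent sections is estimated by
deterministic rasterisation (default grid: 1/96 of the stack's bounding
diagonal) because no polygon-clipping library is part of the package's
dependency footprint; volume is never affected by this approximation.

**Cavalieri / PSI point counting.** A systematic uniform random grid of
pitch `s` (area per point `s²`) is laid over every section with a single
random offset drawn uniformly from `[0, s)²` — the randomness that makes
the estimator `V̂ = t · s² · ΣP` unbiased. Points landing exactly on a
contour boundary (within 10⁻⁹ µm) count one half, the standard
stereological tie-break; strict-interior and inclusive rules are available
for sensitivity analysis. The fractional volume is the pooled ratio
`Vv = ΣP_mes / ΣP_tuft`. Whether one mid-glomerular section or the full
serial stack enters the pool is the caller's choice; the result records
`n_sections` so outputs are unambiguous. The grid extent defaults to the
tuft bounding box padded by one spacing: full coverage without counting
empty space.

**Planimetry.** Profile areas are measured directly from traced polygons
(shoelace formula), averaged per glomerulus, and converted to volume by
extrusion (`V = Ā · t_equiv`, default, with `t_equiv` the section
thickness) or by the Weibel–Gomez shape model `V = (β/k)·Ā^{3/2}`
(β = 1.38, k = 1.1). The model choice is always written into the result,
because the area→volume rule dominates the comparability of
planimetry-based numbers.

## Segmentation model

PAS stains mesangial matrix magenta over a haematoxylin counterstain.
Pixels are converted to optical density `OD = −log₁₀((I+1)/256)` per
channel and unmixed by least squares against a stain matrix (default: the
published PAS and haematoxylin OD vectors, with their cross product as the
residual axis). The PAS channel is thresholded — Otsu on a 256-bin
histogram over the observed range, restricted to tissue pixels (total OD
above `tissue_od_min = 0.1`), unless a manual threshold is supplied — then
cleaned by opening + closing with a 0.5 µm disc, holes filled, and
restricted to the tuft. The tuft itself is defined operationally as the
largest connected component of the morphologically closed (2 µm disc)
tissue mask, filled; this definition is a package choice, recorded in
output metadata, because "total glomerular area" has no standard operational
definition at this resolution. Contours are traced at the 0.5 iso-level
with sub-pixel interpolation and simplified with tolerance
`0.25 · pixel_size`; mesangial regions under `min_region_area_um2 = 5 µm²`
are discarded as sub-biological noise. All defaults are exposed in
`stain_model()` and real slides should calibrate the stain vectors.

## Registration

Successive sections are aligned from matched fiducial landmarks — at least
two pairs, four in routine use — by 2D orthogonal Procrustes restricted to
rotation + translation. Scaling is excluded because serial sections from
one block at one magnification cannot differ in scale, and reflection is
excluded by a sign-corrected SVD because serial sections are never
mirrored. Pairwise fits are composed into a chain with the reference at
the middle of the stack (halving the longest composition path); the
reference convention is written into exported alignment files.
Correspondence is taken from list order — automatic fiducial matching is
out of scope. With `N` noisy fiducials (per-coordinate noise σ) the
expected squared residual per point after fitting the 3 rigid dof is
`σ²(2N−3)/N`, which the suite verifies by simulation.

## The phantom: what it emulates and what it does not

The phantom generates an ellipsoidal tuft voxelized at 0.25 µm (four times
finer than the 1 µm section thickness, so voxelization error is negligible
against estimator error) containing a mesangium built as the level set of
a sum of Gaussian blobs at Poisson-disc-sampled centres; the level is
found by bisection until the realized voxel Vv is within 0.01 of target.
Ground truth — voxel counts × voxel volume, per-section label masks, the
rigid misalignment applied to each section, fiducial coordinates — is
exact by construction. Sections are rendered to RGB through the same
Beer–Lambert stain model the segmenter inverts, with Gaussian pixel noise
(default σ = 5 of 255) and per-section rigid perturbations (σ = 1 µm
translation, 0.02 rad rotation, the scale of careful manual alignment
error). Defaults mirror the targeted acquisition: six 1 µm serial
sections, ~0.25 µm pixels, four fiducials.

The phantom does **not** model capillary lumina, nuclei, podocytes,
staining gradients, section folds or chromatic aberration. Passing tests
therefore demonstrate correctness of the estimators and the pipeline
plumbing — unbiasedness, convergence, invariances, recovery of known
truth under the modelled noise — not segmentation robustness on real
slides, where stain calibration is the user's responsibility.

## Statistical harness

Method comparison uses the design in which each glomerulus is measured by
every method: a one-way within-subject (repeated-measures) ANOVA with
`F = MS_method/MS_error` on `(k−1, (k−1)(n−1))` df, no sphericity
correction by default (the Greenhouse–Geisser epsilon and corrected p are
available by flag and reported alongside, since uncorrected
repeated-measures F is the field's habitual report). Post-hoc contrasts
are paired t-tests on within-unit differences with percent differences
`100·(m_B − m_A)/m_A`, reported raw and Bonferroni-adjusted (the
adjustment convention is otherwise often left unstated). Incomplete units
are dropped listwise with a logged count. Group contrasts of morphometric
records use Welch's t for two groups and one-way ANOVA for more.

## Numerical choices and degenerate inputs

- Polygons with fewer than 3 vertices, zero area or self-intersections are
  rejected at construction — never silently repaired; the segmenter's own
  minimum-area filter handles noise regions.
- Contours are normalized counter-clockwise on construction;
  normalization is idempotent.
- Boundary classification tolerance is fixed at 10⁻⁹ µm, far below pixel
  scale, making point counting deterministic.
- Ear-clipping triangulation takes a fan fast path for convex contours
  and falls back to clipping the most convex corner if floating-point ties
  stall the scan.
- All seeded operations restore the caller's RNG state; phantom child
  seeds derive from the cohort seed by fixed arithmetic (`seed + index`)
  and are logged in the manifest.
- Degenerate statistics are flagged rather than NaN'd: zero within-unit
  error reports an infinite F explicitly; identical paired columns report
  p = 1; groups of size one yield NA tests with a warning.

## Problem sizes used by the tests

The suite exercises the estimators at desk scale, chosen to make every
oracle comparison sharp: a radius-20 µm voxel sphere with 500 systematic
offsets for Cavalieri unbiasedness; 100 random contour stacks for the
extrusion identity; sphere stacks of 5–80 sections for convergence; 1000
replicate fits for registration residuals; a 20-section rendered suite
(two 10-section phantoms) for segmentation fidelity; 20 phantoms for the
erosion-bias demonstration; and 100 replicate cohorts of 22 reduced
phantoms (semi-axes 6×5×4 µm, 0.5 µm voxels) at the albuminuria Vv presets
0.47/0.53/0.76 for the group-ordering check. The cohort phantom is the
smallest geometry whose Vv can still be calibrated to ±0.01, which is what
the replicate study needs.

## Known limitations

- Inter-plane lofting (corresponding-contour tiling) is deliberately not
  implemented; the prism model is the product.
- Contours with holes are unsupported: mesangial regions are traced as
  separate simple polygons, and rare ring-shaped regions are filled.
- The union surface area is raster-estimated, not exact; treat reported
  surface areas as approximations at the stated raster resolution.
- Point counting implements point grids only — line-intercept length
  sampling and vertical-section (cycloid) surface estimation are out of
  scope, as are disector particle counts and analytic CE estimation
  beyond empirical replicate CVs.
- Glomeruli are treated as independent units in the statistics; no
  mixed-effects nesting of glomeruli within patients.
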