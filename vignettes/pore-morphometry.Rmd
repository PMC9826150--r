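---
title: "Cortical pore segmentation and morphometry: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical pore segmentation and morphometry: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremorph)
```

## The measurement problem

A transverse histological section of cortical bone, imaged under
brightfield transmitted light, shows an off-white background outside the
section, mid-gray mineralized tissue, and pore spaces that appear as
near-white lumens ringed by a dark border of deflected lamellae. The
quantities of interest are the cross-sectional envelope areas — total
(Tt.Ar), endosteal/marrow (Es.Ar), cortical (Ct.Ar = Tt.Ar − Es.Ar) — and,
for each pore, its position, size and shape, aggregated by anatomical
region and by pore *type*. Endosteal-adjacent pores formed by coalescing
resorption spaces ("trabecularized" porosity) behave differently from
intracortical ("cortical") porosity, and the two are reported separately.

`poremorph` implements this pipeline as composable, non-interactive
functions. Every prompt of an interactive workflow (axis switches, region
naming, threshold choice) is a function argument with the default behavior
as default.

## Models and rules

### Cortex isolation

The wand selection is a flood fill over the 8-connected component of
pixels within a symmetric brightness window `[v_seed − tol, v_seed + tol]`.
Cleared pixels are set to exact 0, which downstream stages treat as an
inviolable background sentinel (a border threshold never selects value 0).
Border derivation takes the largest nonzero component, fills it to a
silhouette, and calls the largest interior 4-connected hole the marrow.
The asymmetric connectivity (8 for tissue, 4 for holes) prevents a one-pixel
diagonal crack from merging the marrow with the exterior. Auxiliary holes of
at least 9 px² count into Es.Ar; smaller ones are left to be found as pores.
Contours are crack (pixel-edge) polygons, so the shoelace area of a traced
border equals its pixel count exactly and Tt.Ar − Es.Ar equals the cortical
pixel count as an identity, not an approximation.

### Segmentation

Three binarization mechanisms, all restricted to the cortical mask:
lumens (`value > t₁`, near-white), borders (`0 < value < t₂`, dark rings),
and the Phansalkar local threshold for low-contrast images,

> T = m · (1 + p·exp(−q·m) + k·(s/r − 1)),

with `m`, `s` the local mean and standard deviation of the [0, 1]-normalized
image in a disk of radius 15 px (default) and constants k = 0.25, r = 0.5,
p = 2, q = 10 — the published defaults of the algorithm; only the radius is
printed in most workflows, so all four are exposed in `threshold_spec()`.
The default mode is `lumens_plus_borders` (t₁ = 200, t₂ = 100): the union of
lumen cores and border rings closes into complete pore disks, whereas lumens
alone systematically miss the wall and underestimate area.

Morphology is distance-map based: closing by *n* px is one Euclidean
dilation by *n*, hole filling, then one erosion by *n* — a single EDM pass
per direction rather than *n* iterated 3×3 passes, which avoids the
octagonal deformation artifacts of iterated structuring elements at large
*n*. Smoothing is the corresponding EDM opening. Package defaults are 2
closing and 2 smoothing cycles with strict filters `area > 2000 µm²` and
`circularity > 0.300`. The filter values follow a demonstrated workflow
setting; the smoothing default is deliberately small because an opening by
*n* erases any pore of radius below *n* — a 10-cycle smoothing, reasonable
on multi-megapixel slide scans, would delete every pore in a desk-scale
test image.

### Pore typing

The marrow region (principal hole plus auxiliary holes) is converted to an
exact Euclidean distance map — Felzenszwalb's separable lower-envelope
algorithm, no chamfer approximation — and each pore's minimum distance is
the minimum map value over its pixels. The rule is:

> trabecularized ⇔ min Feret diameter ≥ min endosteal distance,

with equality counting as trabecularized. Both sides are compared in
micrometres; pixels are assumed isotropic. A section with no marrow cavity
yields an infinite-distance sentinel and every pore is cortical, with a
logged notice. The map is defined as distance to the nearest marrow
*pixel* (an adjacent pixel is at distance 1); this is the convention the
brute-force oracle in the acceptance suite checks exactly.

### Regions

The principal axis comes from the eigen-decomposition of the cortical
pixels' second-moment tensor; angles are measured in image coordinates
(x right, y down), and "counter-clockwise" means counter-clockwise on
screen. Quadrants are the four half-open 90° sectors `[θ − 45°, θ + 45°)`
etc. around the starting axis; half-openness makes the partition exactly
disjoint and exhaustive, so no boundary pixel is ever dropped or double
counted. Pore assignment renders each region at 255 and takes the arg-max
of the mean value under the pore footprint — arithmetically identical to
maximal overlap-area fraction, and equal to 255/0 scores for interior
pores. Exact 50/50 ties go to the first region in declared name order with
a notice. For ribs, the section is halved along the chosen axis and the
half with the more circular outer silhouette is guessed pleural (it carries
the costal groove); the guess can be overridden with `swap_labels`.

### Morphometry conventions

* **Area**: pixel count × scale²; identical to the shoelace area of the
  crack polygon.
* **Perimeter**: default is the corner-corrected 8-connected boundary
  chain, 0.948 per straight and 1.340 per diagonal step (Kulpa weights).
  A raw (1, √2) chain overestimates a circle's perimeter by ≈ 5%, which
  would push an ideal disk's circularity down to ≈ 0.90; the corrected
  estimator is accurate to ≈ 1% on circles, at the cost of a known
  orientation bias (up to ≈ 5% for edges at exactly 45°). The raw
  rectilinear crack length is available as `perimeter_convention = "crack"`
  and is the convention under which a 10×10 square reports perimeter 40 and
  circularity π/4 exactly.
* **Circularity** 4πA/P², capped at 1 (digital disks can exceed 1 under the
  corrected perimeter). The same capped value is used by the segmentation
  filter.
* **Feret diameters**: rotating-caliper maximum (hull diameter) and minimum
  (minimum width over hull edges) on the convex hull of the crack polygon —
  exact over hull vertices, no angular sampling.
* **Ellipse fit**: orientation and axis ratio from central second moments
  (with the 1/12 per-pixel term), axes rescaled so the ellipse area equals
  the region area; aspect ratio = major/minor, roundness = 4A/(π·major²).
* **Solidity**: A / convex-hull area of the crack polygon. The hull of a
  jagged digital boundary slightly exceeds the pixel union, so even perfect
  digital disks read ≈ 0.92–0.99 depending on radius; solidity is reliable
  for the pore sizes the filters admit (≳ 25 px radius), and the test suite
  asserts the 2%-of-1 property only at those scales.
* **Second moments**: Imin/Imax are the principal centroidal second moments
  of the cortical pixel region (pixel sums plus N/12), exact for
  axis-aligned rectangles; Zpol = (Imin + Imax)/r_max with r_max the
  largest centroid-to-periosteal-vertex distance. Zpol in mm³ — other polar
  modulus conventions exist, and the quantity is clearly labeled so a
  different convention can be substituted downstream.
* **Summary means** are means of per-pore ratios (mean of circularities),
  never ratios of means.

One regional report column deserves a note: the regional "% cortical area"
is computed as region cortical area / total section area × 100, parallel to
the cross-sectional definition; the alternative reading (normalizing by
pore area) is dimensionally inconsistent and was rejected.

## The synthetic world

`section_blueprint()` states the test world once: an 850×850 px annulus at
1 µm/px (outer radius 400 px, endosteal radius 180 px), photometrics
mimicking resin-embedded brightfield appearance (background 245, tissue
150, lumen 240, pore border 60), and 40 circular pores in three concentric
rings (radii drawn uniformly in 27–33 px), angularly staggered so pores
never overlap and always keep ≳ 5 px clear of both cortical surfaces. The
inner ring sits close enough to the marrow that every pore there is
trabecularized by construction, with a type margin of at least ~5 px; the
outer rings are cortical with similar margins — so planted type labels are
decidable outside a 2 px rasterization guard band. Noise is additive
Gaussian (the "moderate" condition uses sd 8 gray levels plus a 10-level
horizontal illumination ramp). All randomness flows from `rng_seed`; the
generator restores the caller's RNG state.

What a green test does establish: every formula and rule above, their
identities and conservation laws, and end-to-end recovery of planted
geometry through the real pipeline code. What it does not: robustness to
real histology — stain variation, resin yellowing, surface debris, cracks,
out-of-focus borders, anisotropic pixels, photomerge seams. The generator
renders ideal circular pores; real resorption bays are irregular, and
threshold defaults tuned here are starting points, not validated settings,
for real slides.

## Numerical choices and degenerate inputs

* Rasterization is even-odd over pixel centers with on-boundary centers
  included — deterministic and epsilon-free, and the round trip
  rasterize(trace(mask)) = mask holds for 4-connected hole-free components.
* The distance transform uses a large finite sentinel (10¹⁵) instead of
  ∞ inside the lower-envelope recursion to keep parabola intersections
  finite; empty-feature inputs are rejected before the kernel runs.
* Constant images pass through contrast operations unchanged (no 0/0).
* A section without nonzero pixels raises "empty section"; a pore polygon
  rasterizing to zero pixels is a degenerate-pore error; pores fully
  outside the cortex are reported as `unassigned` rows, never dropped
  silently.
* Isotropic sections (no defined major axis) fall back to the horizontal
  axis with a warning.
* Archive coordinates are stored as 32-bit floats (sub-pixel resolution
  flag set); the package's own half-integer crack vertices round-trip
  bit-exactly.

## Known limitations

* Perimeter (hence circularity) carries the orientation bias of chain
  estimators; values are comparable within a convention, not across
  conventions.
* The rolling-ball background is the exact morphological opening with a
  ball surface — O(r²) per pixel; very large radii on large images are
  slow, and the paraboloid option is approximated by a flatter ball.
* Multi-plane, compressed, or 16-bit TIFFs are out of scope; images are
  single-plane 8-bit gray or 24-bit RGB.
* Composite ROI records decode to their largest closed subpath; curved
  path segments are rejected.
* No GUI and no interactive editing: manual correction is expected to
  happen in an external ROI editor, with archives exchanged losslessly in
  both directions.
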