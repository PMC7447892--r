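---
title: "Reconstructing and measuring protein precipitate particles from z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and measuring protein precipitate particles from z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precipitr)
```

## The problem

Protein precipitates formed by PEG-induced volume exclusion — for example
antibody flocs produced during a precipitation capture step — are
micron-scale aggregates whose three-dimensional structure controls how they
age under shear, how much surface they expose, and how they redissolve.
Light scattering summarizes a whole suspension by a single average fractal
dimension; electron tomography resolves single particles but is far too slow
for routine process characterization. A wide-field light microscope,
however, can acquire a z-stack of the same field at many focal heights in
seconds. Because out-of-focus content is smeared over many pixels while
in-focus outlines stay sharp, each slice can be segmented down to "what is
in this focal plane", and the stack of segmented slices is a scaled 3D
binary reconstruction of every particle in the field.

`precipitr` implements that reconstruction and the per-particle morphometry
on top of it: box-count fractal dimension, voxel-count volume, minimal
enclosing sphere diameter, packing density and Manhattan surface area, plus
population-level summaries across process conditions. Because real stacks
are rarely shareable, the package also ships a synthetic module — geometric
solids, an off-lattice diffusion-limited aggregation (DLA) simulator, and a
virtual wide-field microscope — so the entire pipeline can be exercised and
validated against known ground truth.

## The measurement model

### Focal-plane segmentation

Each slice is reduced to its in-focus structures by edge detection on the
Prewitt gradient magnitude, thinned to local maxima along the gradient
direction (so edges are one pixel wide) and thresholded. The threshold is
automatic: Otsu's criterion applied to the nonzero thinned gradient
magnitudes, scaled by a user multiplier (`edge_threshold`, default 1).
For whole stacks the Otsu level is pooled over all slices rather than
estimated per slice; a slice that contains only defocused material would
otherwise adapt its threshold downward until blur gradients pass. Edge
maps are then closed with a disc structuring element (`close_radius`,
default 2 px — enough to bridge the 1–4 px gaps typical at ~0.1 µm pixel
pitch), interior holes are filled per slice, and any 2D component touching
the image border is discarded as truncated. Gradient magnitude is
polarity-agnostic, so bright or dark objects segment identically.

### Reconstruction and exclusion filters

Binarized slices are stacked into a `(z, y, x)` boolean volume whose
physical scale comes from a `voxel_geometry` (defaults 0.092 µm/px in x/y,
0.198 µm z-step — a 100×/1.40 oil objective with a piezo z-drive; geometry
is always supplied by the user, never parsed from TIFF metadata, whose
dialects are unreliable). Particles are maximal connected components under
26-connectivity (the "standard connectivity" of common object-detection
routines; 6 and 18 are available). Three filters follow, in fixed order:

1. `remove_small` — components under `min_voxels` (default 50) are
   interference speckle or dust.
2. `remove_border_touching` — components on any volume face (including the
   first/last slice) are likely truncated.
3. `remove_pillars` — interference spots repeat identically in every slice
   regardless of the z-shift and reconstruct as spurious full-height
   columns. A component is a pillar iff it spans at least
   `pillar_min_z_span` (default 0.95) of the slices *and* its per-slice
   footprint nearly equals its xy projection (mean Jaccard ≥ 1 −
   `pillar_max_footprint_dev`, default 0.1). Both conditions are needed: a
   genuine elongated particle can span the stack, but its footprint drifts
   from slice to slice.

The order is deliberate and not interchangeable: a full-height pillar also
touches both z-faces, so in practice the border filter often removes it
first; the pillar rule exists for stacks cropped in z where that is not
the case.

### Morphometry

* **Volume** — voxel count × voxel volume (`dx·dy·dz`), on the original
  anisotropic grid.
* **Diameter** — the exact minimal enclosing sphere of the voxel *centers*
  in physical coordinates (Welzl's move-to-front algorithm; candidates are
  first reduced to per-column z-extremes, which preserves the convex hull).
  Enclosing centers rather than voxel cubes changes diameters by under a
  pixel and keeps the quantity exactly testable; add `dx/√2`-scale padding
  if cube enclosure is wanted.
* **Density** — volume over the enclosing sphere's volume, in (0, 1]; a
  single-voxel particle is 1 by convention. This is a packing fraction:
  actual mass density cannot be obtained from image analysis.
* **Surface area** — exposed voxel faces weighted by their physical areas
  (a Manhattan surface). It is exact on the grid and has a consistent bias
  across particles, which cancels in comparisons; it is not a smoothed
  marching-cubes estimate. Surface/volume proxies surface/mass at constant
  protein density.

### Box-count fractal dimension

The occupied-box count of a fractal obeys `N(ε) ∝ ε^(−D)`. (The relation is
sometimes typeset with a positive exponent; since N falls as boxes grow and
observed dimensions lie in 2–3, the negative-exponent reading is the only
consistent one, and D is reported positive.) `box_count` partitions the
array into ε-sided boxes anchored at the array origin, counting partial
boxes at the far edges; `fit_fractal_dimension` returns minus the OLS slope
of `ln N` on `ln ε`, its r², and the local (adjacent-pair) slopes. The
default ladder is powers of two from 1 up to the smallest side of the
particle's tight bounding box; a `fit_range` can drop the saturated
coarsest points. 3D counting always runs on the isotropically resampled
particle (each slice replicated `round(dz/dx)` times — factor 2 at the
default geometry), since boxes must be cubes.

Monofractality — one dimension across all observed scales — is declared
when r² ≥ 0.98 and no local slope deviates from D by more than 0.15. These
thresholds are package choices; "perfectly linear" log-log curves pass them
comfortably, and a deliberately bifractal fixture (a solid cube with a long
thin rod attached) fails them.

Exact anchors for all of this are cheap and are asserted in the tests: a
filled cube gives D = 3, a filled square 2, a straight rod 1, and a level-3
Menger sponge log 20 / log 3 ≈ 2.7268 on the ladder {1, 3, 9, 27}, each to
1e-6 or better.

### The resolution bias, quantified with pixelated spheres

A perfect sphere should measure D = 3, but rasterization plus box counting
produce artificial surface roughness whose effect grows as particles
shrink. `sphere_calibration` rasterizes solid spheres over a range of radii
and pushes them through the identical analysis. At the default radii
{3, 5, 8, 12, 20, 30} the measured dimensions rise from ≈ 1.97 to ≈ 2.72 —
a bias of up to a full dimension unit at the small end. Two caveats we
found and preserved rather than smoothed over: the rise is not strictly
monotone (r = 12 and r = 20 share the same maximum ladder size but cover it
differently, producing a ~0.02 dip), and a radius-30 sphere still measures
≈ 2.72, not 3. Comparisons of small versus large particles should therefore
use `bias_correct`, which adds `3 − D_sphere(voxel count)` (log-linearly
interpolated from the calibration) and reports the corrected value
alongside — never instead of — the raw one.

## The synthetic module

`generate_solid` rasterizes spheres, cubes, rods and Menger sponges with
closed-form voxel counts. `generate_dla` grows classical particle-cluster
DLA: monomers released from a launch sphere random-walk (step = one monomer
radius) until they first touch the cluster at center distance 2r, where
they stick; walkers beyond three launch radii are relaunched. Walks are
accelerated exactly — a walker provably far from any monomer takes one long
isotropic step instead of many short ones — and are driven by R's RNG, so a
seed fully determines the cluster. Growth follows the expected fractal
mass–radius law: the radius-of-gyration exponent for 4,000–10,000-monomer
clusters falls in 2.2–2.7 (typically ≈ 2.5), the regime expected for
diffusion-limited aggregation of slowly diffusing macromolecules such as
antibodies, as opposed to ≈ 1.7 for reaction-limited growth.

`render_stack` is a virtual wide-field microscope: slice k sees every truth
slice m blurred with σ = √(σ₀² + (a·max(0, |z_k − z_m| − dof/2))²),
combined by maximum projection, plus background, Gaussian noise, and
optional interference spots repeated identically in every slice — the
source of pillar artifacts. The defaults are derived from the acquisition
optics the default geometry implies (100×/1.40 oil, 0.092 µm/px):
diffraction-limited in-focus σ₀ ≈ 0.21 λ/NA ≈ 0.08 µm ≈ 0.9 px; defocus
growth from the geometric aperture cone, σ ≈ ½·tan(asin(NA/n)) ≈ 12 px/µm;
depth of field n·λ/NA² ≈ 0.4 µm. The model is an isotropic distance-scaled
Gaussian blur, not a physical wide-field PSF (no Gibson–Lanni terms, no
spherical aberration); it reproduces the one property the segmentation
relies on — steep gradient decay away from the focal plane — and nothing
else.

What passing the synthetic tests does and does not show: rendered scenes of
well-separated solids are recovered with the correct particle count, voxel
volumes within ~25% (the reconstruction systematically over-segments by a
slice or so of z-smear plus a pixel of xy dilation), and fractal dimensions
within ~0.05–0.1 of the ground-truth particle's own box-count dimension.
Real stacks add optical effects the renderer does not emulate —
shift-variant aberrations, internal self-occlusion of thick particles,
intensity falloff with depth — so these recovery figures are a best case,
not a guarantee.

## Population analysis

Per-particle metrics aggregate by condition: `filter_population` keeps
particles strictly larger than 5,000 voxels (minimizing the resolution bias
above), `summarize_group` reports mean ± sample SD of dimension, density
and surface/volume — the SD is particle-to-particle structural spread, not
a measurement error — and `dimension_histogram` bins the dimension
distribution (0.1-wide bins spanning the data). `rank_conditions` orders
conditions by expected shear and flags whether mean D rises monotonically,
the trend expected if shear strips loose material until flocs densify.
`camp_number` computes the velocity-gradient aging parameter
γ = √(P/(V·ρ·ν)); the printed form of this relation is typeset ambiguously
in the literature this package follows, and the standard square-root
velocity-gradient reading is implemented.

## Numerical choices and edge cases

* Flat images: FFT convolution leaves ~1e-16 gradient noise; magnitudes
  below 1e-8 (relative to the intensity scale) are zeroed so constant
  slices yield exactly empty masks.
* A curve that is flat in log-log space (a single-voxel particle) has zero
  total variance; its fit reports r² = 1 if residuals vanish.
* `remove_small` keeps components with count ≥ threshold; the population
  filter is strict (> 5000), matching its "larger than" definition, and
  voxel counts refer to the original anisotropic grid.
* Histogram bins are right-open with the top edge included, so counts
  always conserve n.
* Voxelized tangent spheres can disconnect: two monomers touching at
  exactly 2r meet at a single point, and the zero-width neck need not
  contain a voxel center. Overlapping monomers always voxelize connected;
  contact-built DLA clusters voxelized at pitch = r split into a few
  dozen 26-components around a dominant one. Label before filtering if
  this matters for a downstream use.
* Box counts use a single grid anchor at the bounding-box origin; on the
  test fixtures, translating the object by up to half a box changes D by
  less than 0.05.

## Known limitations

The box-count estimator needs several decades of scaling to converge. A
10,000-monomer DLA cluster voxelized at one monomer radius offers barely
one clean decade between the monomer cutoff (where counts saturate at one
box per monomer) and the cluster size (where the ladder saturates on the
bounding box), and measures ≈ 1.9 even though the generator's mass-radius
dimension is ≈ 2.5; the gap closes only logarithmically with cluster size
(≈ 2.04 at 100,000 monomers). This is the same size-dependent method bias
the sphere calibration quantifies, seen from the other side, and it is why
population comparisons should be restricted to large particles and read
comparatively rather than as absolute dimensions.

Watershed splitting of touching particles, deconvolution, sub-voxel surface
meshing and multifractal spectra are out of scope.

## Problem sizes used in the test battery

The shipped tests reconstruct scenes up to 48 × 180 × 180 voxels with five
objects, run 100-trial oracle comparisons (box counts ≤ 32³ against a
per-box scan, labeling ≤ 20³ against label propagation, minimal spheres
≤ 50 points against subset enumeration), and grow eight 10,000-monomer DLA
clusters; the full battery completes in a few minutes on one core.
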