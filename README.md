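# precipitr

3D reconstruction and fractal analysis of protein precipitate particles
from wide-field light-microscopy z-stacks.

Protein (e.g. antibody) precipitates formed by PEG volume exclusion are
micron-scale flocs whose structure — how densely they fill space, how much
surface they expose — controls shear aging, recovery and redissolution in a
precipitation capture step. `precipitr` turns a z-stack of one field into
per-particle structure measurements: each slice is binarized by *in-focus
edge detection* (only structures in that slice's focal plane have sharp
gradients), the binarized slices are stacked into a scaled 3D volume,
connected components become particles, and obvious artifacts (tiny specks,
border-truncated objects, interference "pillars" that repeat in every
slice) are filtered out.

Each particle is then characterized by:

* **Box-count fractal dimension** `D`: the occupied-box count follows
  `N(ε) ∝ ε^(−D)`; `D` is minus the log–log slope (3 = solid body,
  lower = branched/porous), with local slopes and an r² threshold as a
  monofractality diagnostic.
* **Volume** = voxel count × voxel volume; **diameter** = exact minimal
  enclosing sphere of the voxel centers; **density** = volume / enclosing
  sphere volume; **surface area** (exposed voxel faces) and
  surface-to-volume ratio.
* Population summaries per process condition: mean ± SD above a
  5000-voxel size threshold, fractal-dimension histograms, shear-ranked
  condition tables, and the Camp number `γ = √(P/(V·ρ·ν))`.

A synthetic module generates ground truth (spheres, cubes, rods, Menger
sponges, and seeded off-lattice diffusion-limited aggregates) and renders
it through a virtual wide-field microscope (defocus blur, noise,
interference spots), so the whole pipeline is testable without microscope
data. A pixelated-sphere calibration quantifies the size-dependent bias of
box counting and provides an optional correction.

## Worked example

Render a two-object scene (a sphere and a cube) through the virtual
microscope and run the full pipeline:

```r
library(precipitr)

g <- voxel_geometry(0.1, 0.1, 0.2)            # um/px in x,y; um per z-step
scene <- array(FALSE, c(36, 110, 110))        # (z, y, x)
ball <- generate_solid("sphere", 10)$voxels
cube <- generate_solid("cube", 16)$voxels
scene[ 8:28,  15:35,  15:35] <- ball
scene[12:27,  65:80,  65:80] <- cube
truth <- binary_volume(scene, g)

stack <- render_stack(truth, microscope_model(noise_sd = 0.02), seed = 2)
res   <- analyze_stack(stack, run_config(), condition = "demo")
res$labeled
#> labeled volume: 36 x 110 x 110 voxels (z,y,x), 2 components
res$metrics[, c("label", "voxel_count", "volume_um3", "diameter_um",
                "density", "fractal_dimension")]
#>   label voxel_count volume_um3 diameter_um density fractal_dimension
#> 1     1        5163      10.33       4.423  0.2280             2.438
#> 2     2        5101      10.20       4.305  0.2443             2.785
```

Both objects are found; recovered voxel counts are within ~25% of the
ground truth (5163 vs 4169 and 5101 vs 4096 — reconstruction smears focus
by about a slice), the sphere (anisotropic voxels make it a 2:1 ellipsoid,
hence density 0.23 inside its enclosing sphere) measures `D ≈ 2.44` and the
cube `D ≈ 2.79`. Rasterization biases `D` downward for small objects; the
sphere calibration quantifies that:

```r
sphere_calibration(c(5, 12, 30))
#>   radius voxel_count dimension     r2
#> 1      5         515     2.053 0.9968
#> 2     12        7153     2.476 0.9958
#> 3     30      113081     2.724 0.9994
```

so a ~5000-voxel *solid* object measuring 2.4–2.8 is consistent with a
compact structure measured at finite resolution; `bias_correct()` adds the
sphere-derived deficit (≈ +0.55 at this size) for explicit comparison.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/precipitr.R simulate --kind dla --n 10000 \
    --monomer-radius 1 --pitch 1 --seed 7 --out truth.tif
Rscript inst/cli/precipitr.R analyze --labels truth.tif \
    --dx 1 --dy 1 --dz 1 --out metrics.csv --curves curves.csv
```

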