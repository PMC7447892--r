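Package: precipitr
Title: 3D Reconstruction and Fractal Analysis of Protein Precipitate Particles
    from Light-Microscopy Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs three-dimensional protein precipitate (floc)
    particles from wide-field light-microscopy z-stacks and characterizes
    each particle by box-count fractal dimension, volume, minimal enclosing
    sphere diameter, packing density and surface area. Slices are binarized
    by in-focus edge detection (Prewitt gradient with non-maximum thinning),
    refined by morphological closing and hole filling, stacked into a scaled
    binary volume, labeled by 3D connected components, and cleaned of
    border-touching objects, small artifacts and z-spanning interference
    pillars. Includes population-level summaries (means and SDs above a
    voxel-count threshold, fractal-dimension histograms, shear-ranked
    condition tables, Camp number), a pixelated-sphere calibration of the
    resolution bias of box counting, and a synthetic module that generates
    ground-truth aggregates (spheres, cubes, rods, Menger sponges,
    diffusion-limited aggregates) and renders them through a virtual
    wide-field microscope for end-to-end validation without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
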