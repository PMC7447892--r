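#' Run the full reconstruction and analysis pipeline on a z-stack
#'
#' Segments every slice by in-focus edge detection, stacks the masks into a
#' scaled binary volume, labels 3D connected components, applies the three
#' exclusion filters in fixed order (small artifacts, border-touching
#' particles, interference pillars), extracts particles and computes the
#' per-particle metrics table. The filter order is fixed and documented;
#' it is not interchangeable.
#'
#' @param stack An [image_stack()].
#' @param config A [run_config()].
#' @param condition Sample tag attached to all particles.
#' @return List with `masks`, `volume`, `labeled` (after all filters),
#'   `particles`, and `metrics` (data frame).
#' @examples
#' \donttest{
#' truth <- generate_solid("sphere", 8, voxel_geometry(1, 1, 1))
#' pad <- array(FALSE, dim(truth$voxels) + 14L)
#' pad[8:(7 + dim(truth$voxels)[1]), 8:(7 + dim(truth$voxels)[2]),
#'     8:(7 + dim(truth$voxels)[3])] <- truth$voxels
#' scene <- binary_volume(pad, voxel_geometry(1, 1, 1))
#' stack <- render_stack(scene, microscope_model(noise_sd = 0.01), seed = 1)
#' res <- analyze_stack(stack, run_config(min_voxels = 20))
#' res$metrics
#' }
#' @export
analyze_stack <- function(stack, config = run_config(), condition = "") {
  stopifnot(inherits(stack, "image_stack"), inherits(config, "run_config"))
  masks <- binarize_stack(stack, config)
  volume <- stack_masks(masks, geometry = stack$geometry)
  labeled <- label_components(volume, connectivity = config$connectivity)
  labeled <- remove_small(labeled, config$min_voxels)
  labeled <- remove_border_touching(labeled)
  labeled <- remove_pillars(labeled, config$pillar_min_z_span,
                            config$pillar_max_footprint_dev)
  particles <- extract_particles(labeled, condition = condition)
  metrics <- particle_metrics_table(particles, config)
  list(masks = masks, volume = volume, labeled = labeled,
       particles = particles, metrics = metrics)
}

#' Long-format box-count curves for a list of particles
#'
#' @param particles List of [particle()] objects.
#' @param config A [run_config()].
#' @return Data frame with columns `label`, `eps_voxels`, `eps_um`, `N`.
#' @export
particle_curves <- function(particles, config = run_config()) {
  rows <- lapply(particles, function(p) {
    arr <- .particle_isotropic_array(p)
    curve <- tryCatch(
      box_count(arr, sizes = .resolve_ladder(config$eps_ladder, arr),
                pitch = p$geometry$dx),
      error = function(e) NULL)
    if (is.null(curve)) return(NULL)
    data.frame(label = p$label, eps_voxels = curve$sizes,
               eps_um = curve$sizes_um, N = curve$counts)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), eps_voxels = numeric(0),
                      eps_um = numeric(0), N = numeric(0))
  out
}
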