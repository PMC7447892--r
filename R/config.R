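#' Run configuration for the reconstruction pipeline
#'
#' Collects every tunable parameter of the segmentation, filtering and
#' box-count steps so a run is fully reproducible from its serialized
#' configuration. All fields have working defaults; see the methods
#' vignette for the rationale behind each.
#'
#' @param edge_threshold Multiplier applied to the automatic (Otsu)
#'   gradient-magnitude level; 1 keeps the automatic level.
#' @param close_radius Radius in pixels of the disc structuring element used
#'   to close gaps between detected edges.
#' @param fill_holes Fill fully enclosed interior holes per slice?
#' @param connectivity 3D neighborhood for object detection: 6, 18 or 26.
#' @param min_voxels Components smaller than this are discarded as
#'   artifacts (dust, interference speckle).
#' @param pillar_min_z_span Fraction of the stack a component must span in z
#'   before it is considered a candidate interference pillar.
#' @param pillar_max_footprint_dev Maximum allowed mean deviation
#'   (1 - Jaccard) of per-slice footprints from the xy projection for a
#'   z-spanning component to be flagged as a pillar.
#' @param eps_ladder Box-size ladder: `"pow2"` (powers of two up to the
#'   smallest bounding-box side) or an explicit integer vector.
#' @param fit_range Optional length-2 numeric, inclusive bounds on the box
#'   sizes used in the log-log fit (`NULL` = all ladder points).
#' @param r2_min,max_local_dev Monofractality thresholds: minimum r-squared
#'   of the log-log fit and maximum absolute deviation of any local
#'   (adjacent-pair) slope from the fitted dimension.
#' @param population_min_voxels Population-level size threshold: only
#'   particles strictly larger than this enter group summaries.
#' @return An object of class `run_config` (a named list).
#' @seealso [read_config()], [write_config()], [write_provenance()]
#' @export
run_config <- function(edge_threshold = 1.0,
                       close_radius = 2L,
                       fill_holes = TRUE,
                       connectivity = 26L,
                       min_voxels = 50L,
                       pillar_min_z_span = 0.95,
                       pillar_max_footprint_dev = 0.1,
                       eps_ladder = "pow2",
                       fit_range = NULL,
                       r2_min = 0.98,
                       max_local_dev = 0.15,
                       population_min_voxels = 5000L) {
  stopifnot(edge_threshold >= 0, close_radius >= 0,
            connectivity %in% c(6L, 18L, 26L), min_voxels >= 0,
            pillar_min_z_span >= 0, pillar_min_z_span <= 1,
            pillar_max_footprint_dev >= 0, pillar_max_footprint_dev <= 1)
  structure(
    list(edge_threshold = edge_threshold,
         close_radius = as.integer(close_radius),
         fill_holes = isTRUE(fill_holes),
         connectivity = as.integer(connectivity),
         min_voxels = as.integer(min_voxels),
         pillar_min_z_span = pillar_min_z_span,
         pillar_max_footprint_dev = pillar_max_footprint_dev,
         eps_ladder = eps_ladder,
         fit_range = fit_range,
         r2_min = r2_min,
         max_local_dev = max_local_dev,
         population_min_voxels = as.integer(population_min_voxels)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("run configuration:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(v)) "<default>" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown
#' keys raise an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a flat YAML file.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to a YAML file
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write run provenance (configuration, geometry, seed, versions) as JSON
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @param geometry Optional [voxel_geometry()] used for the run.
#' @param seed Optional integer seed used for any stochastic step.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path, geometry = NULL, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  prov <- list(
    package = "precipitr",
    version = as.character(utils::packageVersion("precipitr")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    geometry = if (!is.null(geometry))
      unclass(as_geometry(geometry))[c("dx", "dy", "dz")],
    config = unclass(config)
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
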