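# Per-particle morphometrics: voxel-count volume, exact minimal enclosing
# sphere diameter, packing density relative to the enclosing sphere, and
# face-count (Manhattan) surface area. All physical measures use the
# original, anisotropic acquisition geometry.

# physical coordinates (x, y, z) in micrometers of the voxel centers
.particle_points <- function(p) {
  g <- p$geometry
  cbind(x = (p$coords[, 3] - 1) * g$dx,
        y = (p$coords[, 2] - 1) * g$dy,
        z = (p$coords[, 1] - 1) * g$dz)
}

#' Particle volume by voxel counting
#'
#' Volume is the number of voxels contained in the particle multiplied by
#' the volume of one voxel (`dx * dy * dz`).
#'
#' @param p A [particle()].
#' @return List with `voxel_count` and `volume_um3`.
#' @export
particle_volume <- function(p) {
  stopifnot(inherits(p, "particle"))
  n <- nrow(p$coords)
  if (n == 0) stop("empty particle")
  list(voxel_count = n, volume_um3 = n * voxel_volume(p$geometry))
}

#' Exact minimal enclosing sphere of a particle
#'
#' The smallest sphere containing all voxel centers (physical coordinates),
#' computed exactly by Welzl's move-to-front algorithm. Candidate points are
#' first reduced to per-(x,y)-column z-extremes, which preserves the convex
#' hull. Note the sphere encloses voxel *centers*, not voxel cubes; add
#' `dx/sqrt(2)`-scale padding to the diameter if cube enclosure is wanted.
#'
#' @param p A [particle()], or a numeric matrix of points (columns x, y, z,
#'   micrometers).
#' @return List with `center_um` (named x/y/z) and `diameter_um`.
#' @export
min_enclosing_sphere <- function(p) {
  if (inherits(p, "particle")) {
    coords <- p$coords
    # per (j, i) column only the min- and max-z voxels can be hull vertices
    col_id <- paste(coords[, 2], coords[, 3])
    keep <- unlist(lapply(split(seq_len(nrow(coords)), col_id), function(ix) {
      ks <- coords[ix, 1]
      unique(c(ix[which.min(ks)], ix[which.max(ks)]))
    }), use.names = FALSE)
    pts <- .particle_points(particle(p$label, coords[keep, , drop = FALSE],
                                     p$geometry, p$condition))
  } else {
    pts <- as.matrix(p)
    stopifnot(is.numeric(pts), ncol(pts) == 3, nrow(pts) >= 1)
  }
  res <- .miniball_cpp(pts)
  list(center_um = c(x = res[1], y = res[2], z = res[3]),
       diameter_um = 2 * res[4])
}

#' Particle packing density
#'
#' Fraction of the minimal enclosing sphere filled by the particle:
#' `volume / ((pi/6) * diameter^3)`, clipped to at most 1. A single-voxel
#' particle (diameter 0) has density 1 by convention.
#'
#' @param p A [particle()].
#' @return Density in `(0, 1]`.
#' @export
particle_density <- function(p) {
  stopifnot(inherits(p, "particle"))
  v <- particle_volume(p)
  d <- min_enclosing_sphere(p)$diameter_um
  if (d <= 0) return(1)
  min(1, v$volume_um3 / ((pi / 6) * d^3))
}

#' Particle surface area by face counting
#'
#' Every voxel face shared between foreground and background (or the volume
#' edge) contributes its physical area: `dy*dz` for x-facing, `dx*dz` for
#' y-facing, `dx*dy` for z-facing faces. This Manhattan surface is exact on
#' the voxel grid and has a consistent bias across particles; it is not a
#' smoothed (marching-cubes) estimate.
#'
#' @param p A [particle()].
#' @return Surface area in square micrometers.
#' @export
surface_area <- function(p) {
  stopifnot(inherits(p, "particle"))
  arr <- particle_array(p)
  g <- p$geometry
  d <- dim(arr)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  exposed <- function(offset) {
    shifted <- pad[(2:(d[1] + 1)) + offset[1],
                   (2:(d[2] + 1)) + offset[2],
                   (2:(d[3] + 1)) + offset[3], drop = FALSE]
    sum(arr & !shifted)
  }
  n_z <- exposed(c(1, 0, 0)) + exposed(c(-1, 0, 0))  # faces normal to z
  n_y <- exposed(c(0, 1, 0)) + exposed(c(0, -1, 0))
  n_x <- exposed(c(0, 0, 1)) + exposed(c(0, 0, -1))
  n_z * g$dx * g$dy + n_y * g$dx * g$dz + n_x * g$dy * g$dz
}

#' Surface-to-volume ratio
#'
#' Surface area divided by filled volume, a proxy for surface-to-mass at
#' constant protein density. Decreases with particle size for a fixed shape
#' family.
#'
#' @param p A [particle()].
#' @return Ratio in inverse micrometers.
#' @export
surface_to_volume <- function(p) {
  surface_area(p) / particle_volume(p)$volume_um3
}

#' Compute the full metrics row for one particle
#'
#' Combines voxel-count volume, minimal-sphere diameter, density, surface
#' measures and the box-count fractal dimension (computed on the
#' isotropically resampled particle) into one data-frame row matching the
#' [write_metrics()] schema.
#'
#' @param p A [particle()].
#' @param config A [run_config()] (box-count ladder, fit range and
#'   monofractality thresholds).
#' @return One-row data frame.
#' @export
particle_metrics <- function(p, config = run_config()) {
  stopifnot(inherits(p, "particle"))
  v <- particle_volume(p)
  sph <- min_enclosing_sphere(p)
  dens <- if (sph$diameter_um <= 0) 1 else
    min(1, v$volume_um3 / ((pi / 6) * sph$diameter_um^3))
  sa <- surface_area(p)
  arr <- .particle_isotropic_array(p)
  fit <- tryCatch({
    curve <- box_count(arr, sizes = .resolve_ladder(config$eps_ladder, arr),
                       pitch = p$geometry$dx)
    fit_fractal_dimension(curve, fit_range = config$fit_range,
                          r2_min = config$r2_min,
                          max_local_dev = config$max_local_dev)
  }, error = function(e) NULL)
  data.frame(
    label = p$label,
    voxel_count = v$voxel_count,
    volume_um3 = v$volume_um3,
    diameter_um = sph$diameter_um,
    density = dens,
    surface_area_um2 = sa,
    surface_to_volume_per_um = sa / v$volume_um3,
    fractal_dimension = if (is.null(fit)) NA_real_ else fit$dimension,
    fit_r2 = if (is.null(fit)) NA_real_ else fit$r2,
    monofractal_flag = if (is.null(fit)) NA else fit$monofractal_flag,
    condition = p$condition,
    stringsAsFactors = FALSE
  )
}

#' Metrics table for a list of particles
#'
#' @param particles List of [particle()] objects.
#' @param config A [run_config()].
#' @return Data frame with one row per particle, in input order.
#' @export
particle_metrics_table <- function(particles, config = run_config()) {
  if (length(particles) == 0) {
    return(as.data.frame(setNames(
      rep(list(logical(0)), length(.metric_columns)), .metric_columns)))
  }
  do.call(rbind, lapply(particles, particle_metrics, config = config))
}
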