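#' Voxel geometry of an acquisition
#'
#' Physical pitch of a z-stack: micrometers per pixel in x and y, and the
#' z-step between consecutive focal planes. All micrometer-scale outputs
#' (volumes, diameters, surface areas) are anchored to this geometry.
#' Voxel `(k, j, i)` (z, y, x; 0-based) has its center at physical
#' coordinate `(k*dz, j*dy, i*dx)`.
#'
#' @param dx,dy Micrometers per pixel in x and y. Default 0.092.
#' @param dz Micrometers per z-step. Default 0.198.
#' @return An object of class `voxel_geometry` with fields `dx`, `dy`, `dz`
#'   and the recorded anisotropy ratio `dz/dx`.
#' @examples
#' g <- voxel_geometry()         # 100x oil objective defaults
#' g$anisotropy                  # dz / dx
#' @export
voxel_geometry <- function(dx = 0.092, dy = 0.092, dz = 0.198) {
  stopifnot(is.numeric(dx), is.numeric(dy), is.numeric(dz),
            length(dx) == 1, length(dy) == 1, length(dz) == 1)
  if (!all(is.finite(c(dx, dy, dz))) || dx <= 0 || dy <= 0 || dz <= 0)
    stop("voxel pitches dx, dy, dz must be positive and finite")
  structure(
    list(dx = dx, dy = dy, dz = dz, anisotropy = dz / dx),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "voxel geometry: dx = %g um, dy = %g um, dz = %g um (dz/dx = %.3f)\n",
    x$dx, x$dy, x$dz, x$anisotropy))
  invisible(x)
}

#' @export
format.voxel_geometry <- function(x, ...) {
  sprintf("%g x %g x %g um", x$dx, x$dy, x$dz)
}

voxel_volume <- function(geometry) geometry$dx * geometry$dy * geometry$dz

as_geometry <- function(x) {
  if (inherits(x, "voxel_geometry")) return(x)
  if (is.numeric(x) && length(x) == 3)
    return(voxel_geometry(x[1], x[2], x[3]))
  stop("cannot interpret object as voxel geometry")
}
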