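# Synthetic ground truth: geometric solids, off-lattice diffusion-limited
# aggregates, and a virtual wide-field microscope that renders a binary
# volume into a z-stack with defocus blur, background, noise and z-spanning
# interference spots. Provides fixtures with known answers for every stage
# of the pipeline.

#' Generate a rasterized solid
#'
#' Deterministic voxelizations on an isotropic grid:
#' * `sphere` — voxel centers within the analytic radius (`size` = radius);
#'   array side `2*size + 1`.
#' * `cube` — filled cube of side `size`.
#' * `rod` — straight 1-voxel-wide rod of length `size` along x.
#' * `menger` — Menger sponge of level `size` (side `3^size`,
#'   `20^size` foreground voxels).
#'
#' @param kind `"sphere"`, `"cube"`, `"rod"` or `"menger"`.
#' @param size Radius, side, length or level (menger level <= 4).
#' @param geometry A [voxel_geometry()]; defaults to an isotropic unit grid.
#' @return A [binary_volume()].
#' @examples
#' sum(generate_solid("menger", 3)$voxels)  # 20^3 = 8000
#' @export
generate_solid <- function(kind = c("sphere", "cube", "rod", "menger"),
                           size, geometry = voxel_geometry(1, 1, 1)) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(size), length(size) == 1, size >= 1)
  vox <- switch(kind,
    sphere = {
      r <- size
      n <- 2L * floor(r) + 1L
      c0 <- floor(r) + 1L
      ax <- (seq_len(n) - c0)^2
      outer(outer(ax, ax, "+"), ax, "+") <= r^2
    },
    cube = array(TRUE, rep(as.integer(size), 3)),
    rod = array(TRUE, c(1L, 1L, as.integer(size))),
    menger = {
      level <- as.integer(size)
      if (level > 4) stop("menger level must be <= 4")
      side <- 3L^level
      # cell kept iff at no base-3 digit position do two or more of the
      # three coordinates have digit 1
      idx <- seq_len(side) - 1L
      keep1 <- matrix(TRUE, side, level)   # per-axis digit == 1 indicator
      for (l in seq_len(level))
        keep1[, l] <- (idx %/% 3L^(l - 1L)) %% 3L == 1L
      vox <- array(TRUE, c(side, side, side))
      for (l in seq_len(level)) {
        d1 <- keep1[, l]
        rem <- outer(outer(d1, d1, "+"), d1, "+") >= 2
        vox[rem] <- FALSE
      }
      vox
    })
  binary_volume(vox, geometry)
}

#' Generate an off-lattice particle-cluster diffusion-limited aggregate
#'
#' Classical particle-cluster DLA: monomers released one at a time from a
#' launch sphere just outside the cluster random-walk (step length = one
#' monomer radius; single long steps while provably far from any contact)
#' until they touch the cluster (center distance `2r`) and stick.
#' Walkers drifting beyond the kill radius (3 x launch radius) are
#' relaunched. Diffusion-limited growth of this kind yields aggregates with
#' mass-radius dimension near 2.5, the regime expected for precipitation of
#' slowly diffusing macromolecules such as antibodies.
#'
#' @param n_monomers Number of monomers (>= 2).
#' @param monomer_radius Monomer radius (length units of the point cloud).
#' @param seed Integer seed; the output is fully determined by it.
#' @return Numeric matrix of monomer centers (columns x, y, z) with
#'   attributes `monomer_radius` and `seed`.
#' @export
generate_dla <- function(n_monomers, monomer_radius = 1, seed = 1L) {
  stopifnot(n_monomers >= 2, monomer_radius > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  pts <- .dla_cpp(as.integer(n_monomers), monomer_radius)
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "monomer_radius") <- monomer_radius
  attr(pts, "seed") <- as.integer(seed)
  pts
}

#' Voxelize a point cloud of monomers
#'
#' A voxel is foreground iff its center lies within `monomer_radius` of any
#' monomer center. The grid is isotropic with the given pitch and the
#' bounding box is padded by 2 voxels on every side.
#'
#' @param points Numeric matrix of monomer centers (columns x, y, z).
#' @param monomer_radius Monomer radius, same units as `points`.
#' @param pitch Voxel edge length, same units as `points`.
#' @return A [binary_volume()] with geometry `pitch` in all three axes.
#' @export
voxelize <- function(points, monomer_radius = attr(points, "monomer_radius"),
                     pitch = 1) {
  pts <- as.matrix(points)
  stopifnot(is.numeric(pts), ncol(pts) == 3, nrow(pts) >= 1,
            monomer_radius > 0, pitch > 0)
  r <- monomer_radius
  # voxel i (1-based) center = origin + (i - 1) * pitch, per axis
  origin <- floor((apply(pts, 2, min) - r) / pitch) * pitch - 2 * pitch
  hi <- ceiling((apply(pts, 2, max) + r) / pitch) * pitch + 2 * pitch
  dims <- as.integer(round((hi - origin) / pitch)) + 1L
  w <- ceiling(r / pitch)
  off <- as.matrix(expand.grid(dx = -w:w, dy = -w:w, dz = -w:w))
  marked <- lapply(seq_len(nrow(pts)), function(m) {
    cv <- round((pts[m, ] - origin) / pitch) + 1   # nearest voxel index
    cand <- sweep(off, 2, cv, "+")
    centers <- sweep((cand - 1) * pitch, 2, origin, "+")
    d2 <- rowSums((centers - matrix(pts[m, ], nrow(cand), 3,
                                    byrow = TRUE))^2)
    ok <- d2 <= r^2 &
      cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    cand[ok, , drop = FALSE]
  })
  cand <- do.call(rbind, marked)
  vox <- array(FALSE, dims[c(3, 2, 1)])            # (z, y, x)
  vox[cbind(cand[, 3], cand[, 2], cand[, 1])] <- TRUE
  out <- binary_volume(vox, voxel_geometry(pitch, pitch, pitch))
  attr(out, "origin") <- origin
  out
}

#' Virtual wide-field microscope model
#'
#' Parameters of the synthetic z-stack renderer: in-focus blur, linear
#' growth of defocus blur with distance from the focal plane, a depth of
#' field inside which content stays sharp, additive Gaussian noise,
#' background level, and a number of interference spots that repeat
#' identically in every slice (the source of pillar artifacts).
#'
#' @param in_focus_sigma Blur sigma (pixels) applied to in-focus content.
#' @param defocus_sigma_per_um Blur growth (pixels per micrometer of
#'   distance beyond the depth of field).
#' @param depth_of_field Micrometers within which content is in focus.
#' @param noise_sd Additive Gaussian noise SD (intensity fraction).
#' @param background_level Background intensity in `[0, 1]`.
#' @param interference_spots Number of z-spanning artifact spots.
#' @details Defaults follow the acquisition optics of a 100x/1.40 oil
#' objective at 0.092 um/px: in-focus blur is the diffraction-limited PSF
#' (`0.21 * lambda / NA` ~ 0.08 um ~ 0.9 px), the defocus blur grows with
#' the geometric cone of the aperture (sigma ~ half the cone radius
#' `tan(asin(NA/n))` ~ 13 px/um, rounded to 12), and the depth of field is
#' `n * lambda / NA^2` ~ 0.4 um.
#' @return An object of class `microscope_model`.
#' @export
microscope_model <- function(in_focus_sigma = 0.9,
                             defocus_sigma_per_um = 12,
                             depth_of_field = 0.4,
                             noise_sd = 0.02,
                             background_level = 0.1,
                             interference_spots = 0L) {
  vals <- c(in_focus_sigma, defocus_sigma_per_um, depth_of_field,
            noise_sd, background_level, interference_spots)
  if (any(vals < 0)) stop("all microscope model parameters must be >= 0")
  structure(
    list(in_focus_sigma = in_focus_sigma,
         defocus_sigma_per_um = defocus_sigma_per_um,
         depth_of_field = depth_of_field,
         noise_sd = noise_sd,
         background_level = background_level,
         interference_spots = as.integer(interference_spots)),
    class = "microscope_model"
  )
}

.gauss_blur <- function(m, sigma) {
  if (sigma < 0.05) return(m)
  # kernel must fit inside the slice; clamp for extreme defocus
  half <- min(ceiling(3 * sigma), (min(dim(m)) - 1) %/% 2)
  EBImage::gblur(m, sigma = sigma, radius = 2 * half + 1,
                 boundary = "replicate")
}

#' Render a ground-truth volume into a synthetic z-stack
#'
#' Emulates wide-field acquisition: for output slice `k`, every truth slice
#' `m` contributes its silhouette blurred with sigma
#' `sqrt(s0^2 + (a * max(0, |z_k - z_m| - dof/2))^2)` (s0 = in-focus sigma,
#' a = defocus growth), combined by maximum projection; then background,
#' additive Gaussian noise, and `interference_spots` bright discs repeated
#' identically in every slice are added and intensities clipped to [0, 1].
#'
#' @param truth A [binary_volume()] (the ground-truth object scene).
#' @param model A [microscope_model()].
#' @param seed Integer seed for noise and spot placement.
#' @return An [image_stack()] with the truth's geometry.
#' @export
render_stack <- function(truth, model = microscope_model(), seed = 1L) {
  stopifnot(inherits(truth, "binary_volume"),
            inherits(model, "microscope_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  g <- truth$geometry
  d <- dim(truth$voxels)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  sil <- lapply(seq_len(nz), function(m) {
    s <- truth$voxels[m, , , drop = TRUE] * 1
    if (sum(s) == 0) NULL else s
  })
  # blur sigma depends only on the slice distance
  sigma_d <- vapply(0:(nz - 1), function(dk) {
    dist_um <- max(0, dk * g$dz - model$depth_of_field / 2)
    sqrt(model$in_focus_sigma^2 +
           (model$defocus_sigma_per_um * dist_um)^2)
  }, numeric(1))
  # interference spots: same discs in every slice
  spots <- matrix(0, ny, nx)
  if (model$interference_spots > 0) {
    for (s in seq_len(model$interference_spots)) {
      cy <- runif(1, 0.15, 0.85) * ny
      cx <- runif(1, 0.15, 0.85) * nx
      rad <- runif(1, 2.5, 4.5)
      yy <- matrix(seq_len(ny), ny, nx)
      xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
      spots <- pmax(spots, 0.85 * ((yy - cy)^2 + (xx - cx)^2 <= rad^2))
    }
  }
  slices <- vector("list", nz)
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nz)) {
    acc <- matrix(0, ny, nx)
    for (m in seq_len(nz)) {
      if (is.null(sil[[m]])) next
      dk <- abs(k - m)
      key <- paste0(m, ":", dk)
      bl <- cache[[key]]
      if (is.null(bl)) {
        bl <- .gauss_blur(sil[[m]], sigma_d[dk + 1])
        cache[[key]] <- bl
      }
      acc <- pmax(acc, bl)
    }
    img <- model$background_level + acc
    img <- pmax(img, model$background_level + spots)
    if (model$noise_sd > 0)
      img <- img + matrix(rnorm(ny * nx, 0, model$noise_sd), ny, nx)
    img[img < 0] <- 0; img[img > 1] <- 1
    slices[[k]] <- img
  }
  image_stack(slices, geometry = g, name = "synthetic render")
}
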