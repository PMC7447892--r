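# Stacking of slice masks into a scaled 3D binary volume, connected-component
# particle extraction, and the three exclusion filters (small artifacts,
# border-touching particles, z-spanning interference pillars).
#
# Axis order is (z, y, x) throughout; voxel (k, j, i), 0-based, has its
# center at physical coordinate (k*dz, j*dy, i*dx).

#' Construct a binary volume
#'
#' @param voxels Logical 3D array in (z, y, x) order.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, geometry = voxel_geometry()) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  mode(voxels) <- "logical"
  structure(list(voxels = voxels, geometry = as_geometry(geometry)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("binary volume: %d x %d x %d voxels (z,y,x), %s, %d foreground\n",
              d[1], d[2], d[3], format(x$geometry), sum(x$voxels)))
  invisible(x)
}

#' Stack slice masks into a scaled 3D binary volume
#'
#' Voxel `(k, j, i)` is foreground iff pixel `(j, i)` of mask `k` is
#' foreground; slices are spaced by the z-step of the geometry.
#'
#' @param masks Ordered list of `slice_mask` (or logical matrices) sharing
#'   dimensions, in acquisition order.
#' @param geometry A [voxel_geometry()]; defaults to the geometry carried by
#'   the first mask, if any.
#' @return A [binary_volume()].
#' @export
stack_masks <- function(masks, geometry = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1)
  if (is.null(geometry)) {
    geometry <- attr(masks[[1]], "geometry")
    if (is.null(geometry)) geometry <- voxel_geometry()
  }
  d1 <- dim(masks[[1]])
  for (k in seq_along(masks))
    if (!identical(dim(masks[[k]]), d1))
      stop(sprintf("slice %d has dimensions %s, expected %s", k,
                   paste(dim(masks[[k]]), collapse = "x"),
                   paste(d1, collapse = "x")))
  arr <- array(unlist(lapply(masks, as.logical), use.names = FALSE),
               dim = c(d1[1], d1[2], length(masks)))   # (y, x, z)
  binary_volume(aperm(arr, c(3, 1, 2)), geometry = geometry)
}

#' Label connected components of a binary volume
#'
#' Maximal connected components under the chosen 3D neighborhood. The
#' default, 26-connectivity (faces, edges and corners), is the standard
#' connectivity of common object-detection routines.
#'
#' @param volume A [binary_volume()].
#' @param connectivity 6, 18 or 26.
#' @return A `labeled_volume`: integer array `labels` (0 = background,
#'   1..K = particles), `geometry`, and component count `n`.
#' @export
label_components <- function(volume, connectivity = 26L) {
  stopifnot(inherits(volume, "binary_volume"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(volume$voxels)
  lab <- .label3d_cpp(as.logical(volume$voxels), d[1], d[2], d[3],
                      as.integer(connectivity))
  n <- attr(lab, "n_components")
  labeled_volume(array(as.integer(lab), d), volume$geometry, n)
}

labeled_volume <- function(labels, geometry, n = max(labels, 0L)) {
  structure(list(labels = labels, geometry = as_geometry(geometry),
                 n = as.integer(n)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled volume: %d x %d x %d voxels (z,y,x), %d components\n",
              d[1], d[2], d[3], x$n))
  invisible(x)
}

# relabel surviving labels to contiguous 1..K preserving original order
.compact_labels <- function(labeled, keep) {
  lab <- labeled$labels
  if (length(keep) == 0) {
    lab[] <- 0L
    return(labeled_volume(lab, labeled$geometry, 0L))
  }
  map <- integer(labeled$n)
  map[keep] <- seq_along(keep)
  fg <- lab > 0L
  lab[fg] <- map[lab[fg]]
  labeled_volume(lab, labeled$geometry, length(keep))
}

.label_sizes <- function(labeled) {
  if (labeled$n == 0) return(integer(0))
  tabulate(labeled$labels[labeled$labels > 0L], nbins = labeled$n)
}

#' Remove components smaller than a voxel-count threshold
#'
#' Components with fewer than `min_voxels` voxels are relabeled to
#' background; surviving labels are compacted to 1..K.
#'
#' @param labeled A `labeled_volume`.
#' @param min_voxels Minimum voxel count (components below it are dropped).
#' @return A `labeled_volume`.
#' @export
remove_small <- function(labeled, min_voxels = 50L) {
  stopifnot(inherits(labeled, "labeled_volume"), min_voxels >= 0)
  sizes <- .label_sizes(labeled)
  .compact_labels(labeled, which(sizes >= min_voxels))
}

#' Remove components touching any face of the volume
#'
#' Components with a voxel on any of the six volume faces (including the
#' first and last z-slice) are likely truncated and are removed.
#'
#' @param labeled A `labeled_volume`.
#' @return A `labeled_volume`.
#' @export
remove_border_touching <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_volume"))
  lab <- labeled$labels
  d <- dim(lab)
  on_border <- unique(c(lab[1, , ], lab[d[1], , ],
                        lab[, 1, ], lab[, d[2], ],
                        lab[, , 1], lab[, , d[3]]))
  on_border <- on_border[on_border > 0L]
  keep <- setdiff(seq_len(labeled$n), on_border)
  .compact_labels(labeled, keep)
}

#' Remove z-spanning interference pillars
#'
#' Interference spots repeat identically in every slice of a series
#' regardless of the z-shift and reconstruct as spurious columns spanning
#' the whole volume. A component is removed iff (a) its z-extent covers at
#' least `min_z_span_fraction` of the slices AND (b) its per-slice footprint
#' is nearly identical to its overall xy projection: mean Jaccard similarity
#' >= 1 - `max_footprint_jaccard_dev` over the slices it occupies.
#'
#' @param labeled A `labeled_volume`.
#' @param min_z_span_fraction Minimum z-extent fraction, in `[0, 1]`.
#' @param max_footprint_jaccard_dev Maximum mean footprint deviation.
#' @return A `labeled_volume`.
#' @export
remove_pillars <- function(labeled, min_z_span_fraction = 0.95,
                           max_footprint_jaccard_dev = 0.1) {
  stopifnot(inherits(labeled, "labeled_volume"),
            min_z_span_fraction >= 0, min_z_span_fraction <= 1,
            max_footprint_jaccard_dev >= 0, max_footprint_jaccard_dev <= 1)
  lab <- labeled$labels
  d <- dim(lab)
  nz <- d[1]
  if (labeled$n == 0) return(labeled)
  idx <- which(lab > 0L, arr.ind = TRUE)
  lb <- lab[lab > 0L]
  drop <- logical(labeled$n)
  for (l in seq_len(labeled$n)) {
    sel <- lb == l
    ks <- idx[sel, 1]
    span <- max(ks) - min(ks) + 1L
    if (span < min_z_span_fraction * nz) next
    foot <- idx[sel, 2:3, drop = FALSE]          # (j, i) per voxel
    pix <- (foot[, 1] - 1L) + d[2] * (foot[, 2] - 1L)  # linear xy pixel
    proj <- unique(pix)
    jac <- vapply(split(pix, ks), function(p) {
      length(unique(p)) / length(proj)           # footprint is subset of proj
    }, numeric(1))
    # slices in the z-extent where the component is absent count as 0
    mean_jac <- sum(jac) / span
    if (mean_jac >= 1 - max_footprint_jaccard_dev) drop[l] <- TRUE
  }
  .compact_labels(labeled, which(!drop))
}

#' Extract particles from a labeled volume
#'
#' One `particle` per surviving label, sorted by voxel count (largest
#' first), each carrying its voxel indices, bounding box, geometry and a
#' free-text condition tag.
#'
#' @param labeled A `labeled_volume`.
#' @param condition Sample tag attached to every particle (e.g.
#'   `"batch_low_shear"`).
#' @return List of `particle` objects.
#' @export
extract_particles <- function(labeled, condition = "") {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (labeled$n == 0) return(list())
  idx <- which(labeled$labels > 0L, arr.ind = TRUE)
  lb <- labeled$labels[labeled$labels > 0L]
  parts <- lapply(seq_len(labeled$n), function(l) {
    coords <- idx[lb == l, , drop = FALSE]
    colnames(coords) <- c("k", "j", "i")
    particle(label = l, coords = coords, geometry = labeled$geometry,
             condition = condition)
  })
  ord <- order(vapply(parts, function(p) nrow(p$coords), integer(1)),
               decreasing = TRUE)
  parts[ord]
}

#' Construct a particle from voxel indices
#'
#' @param label Integer label.
#' @param coords Integer matrix of 1-based voxel indices, columns
#'   `(k, j, i)` = (z, y, x).
#' @param geometry A [voxel_geometry()].
#' @param condition Free-text sample tag.
#' @return An object of class `particle`.
#' @export
particle <- function(label, coords, geometry = voxel_geometry(),
                     condition = "") {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 1)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("k", "j", "i")
  bbox <- rbind(lo = apply(coords, 2, min), hi = apply(coords, 2, max))
  structure(list(label = as.integer(label), coords = coords,
                 bounding_box = bbox, geometry = as_geometry(geometry),
                 condition = condition),
            class = "particle")
}

#' @export
print.particle <- function(x, ...) {
  b <- x$bounding_box
  cat(sprintf(
    "particle %d: %d voxels, bbox %dx%dx%d (z,y,x), condition '%s'\n",
    x$label, nrow(x$coords),
    b[2, 1] - b[1, 1] + 1L, b[2, 2] - b[1, 2] + 1L, b[2, 3] - b[1, 3] + 1L,
    x$condition))
  invisible(x)
}

# tight bounding-box logical array of a particle, (z, y, x)
particle_array <- function(p) {
  b <- p$bounding_box
  d <- b[2, ] - b[1, ] + 1L
  arr <- array(FALSE, d)
  arr[cbind(p$coords[, 1] - b[1, 1] + 1L,
            p$coords[, 2] - b[1, 2] + 1L,
            p$coords[, 3] - b[1, 3] + 1L)] <- TRUE
  arr
}

#' Resample a binary volume to isotropic voxels
#'
#' Box counting assumes cubic cells while acquisition voxels are anisotropic
#' (dz > dx). Each slice is replicated `round(dz/dx)` times along z
#' (nearest-neighbor), after which the z-pitch is `dz / round(dz/dx)`.
#' Volumes with `dz < dx` are returned unchanged with a warning
#' (downsampling is not supported); already-isotropic volumes are returned
#' unchanged.
#'
#' @param volume A [binary_volume()].
#' @return A [binary_volume()] with (near-)isotropic geometry.
#' @export
resample_isotropic <- function(volume) {
  stopifnot(inherits(volume, "binary_volume"))
  g <- volume$geometry
  if (g$dz < g$dx) {
    warning("dz < dx: z-downsampling not supported, returning input")
    return(volume)
  }
  f <- round(g$dz / g$dx)
  if (f <= 1) return(volume)
  vox <- volume$voxels[rep(seq_len(dim(volume$voxels)[1]), each = f), , ,
                       drop = FALSE]
  binary_volume(vox, voxel_geometry(g$dx, g$dy, g$dz / f))
}

# isotropic z-replication of a particle's tight bounding-box array
.particle_isotropic_array <- function(p) {
  arr <- particle_array(p)
  g <- p$geometry
  f <- if (g$dz >= g$dx) round(g$dz / g$dx) else 1
  if (f > 1) arr <- arr[rep(seq_len(dim(arr)[1]), each = f), , ,
                        drop = FALSE]
  arr
}
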