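# In-focus edge segmentation of individual z-slices.
#
# Out-of-focus content in a wide-field stack is smeared over many pixels, so
# its intensity gradients are shallow; structures in the focal plane keep
# sharp outlines. Thresholding the Prewitt gradient magnitude (after
# non-maximum thinning) therefore selects only in-focus outlines, which are
# then closed, filled, and cleared of border-touching objects.

# shift a matrix by (dy, dx), padding with `fill`
.shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Otsu threshold of a numeric vector (maximize between-class variance)
.otsu <- function(v, n_bins = 256) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(0)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  h <- hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

.prewitt_gradient <- function(img) {
  kx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)  # d/dx (columns)
  ky <- t(kx)                                          # d/dy (rows)
  gx <- as.matrix(EBImage::filter2(img, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, ky, boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  # suppress FFT round-off so flat regions have exactly zero gradient
  eps <- 1e-8 * max(1, max(abs(img)))
  mag[mag < eps] <- 0
  list(gx = gx, gy = gy, mag = mag)
}

# suppress gradient magnitudes that are not local maxima along the gradient
# direction (quantized to 0/45/90/135 degrees)
.nonmax_suppress <- function(mag, gx, gy) {
  ang <- atan2(gy, gx)              # rows are y, columns are x
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  # sector 0: gradient along x -> compare left/right neighbors
  steps <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (s in 0:3) {
    d <- steps[[s + 1]]
    n1 <- .shift_mat(mag, d[1], d[2], fill = 0)
    n2 <- .shift_mat(mag, -d[1], -d[2], fill = 0)
    keep[sector == s & mag >= n1 & mag >= n2] <- TRUE
  }
  mag * keep
}

#' Detect edges lying in the focal plane of a single slice
#'
#' Prewitt gradient magnitude, thinned to local maxima along the gradient
#' direction and thresholded. Blurred (out-of-focus) structures have shallow
#' gradients and fall below the threshold, so only in-focus outlines remain.
#'
#' @param slice Numeric matrix of grayscale intensities.
#' @param threshold Multiplier on the automatic level (Otsu on the nonzero
#'   thinned gradient magnitudes). Ignored when `abs_threshold` is given.
#' @param abs_threshold Absolute gradient-magnitude threshold; used as-is.
#'   [binarize_stack()] passes a level pooled over the whole stack here.
#' @return Logical matrix of edge pixels (same size as `slice`).
#' @examples
#' img <- matrix(0, 48, 48)
#' img[16:32, 16:32] <- 1                 # sharp-edged square
#' edges <- detect_focal_edges(img)
#' sum(edges) > 0
#' @export
detect_focal_edges <- function(slice, threshold = 1.0,
                               abs_threshold = NULL) {
  stopifnot(is.matrix(slice), length(slice) > 0, threshold >= 0)
  g <- .prewitt_gradient(slice)
  thin <- .nonmax_suppress(g$mag, g$gx, g$gy)
  if (is.null(abs_threshold)) {
    pos <- thin[thin > 0]
    if (length(pos) == 0) return(matrix(FALSE, nrow(slice), ncol(slice)))
    level <- .otsu(pos) * threshold
  } else {
    level <- abs_threshold
  }
  thin > level
}

#' Close gaps between nearby edges
#'
#' Morphological closing (dilation then erosion) with a disc structuring
#' element, bridging small breaks in detected outlines.
#'
#' @param edges Logical matrix (edge map).
#' @param radius Disc radius in pixels; 0 is the identity.
#' @return Logical matrix.
#' @export
close_edges <- function(edges, radius = 2L) {
  stopifnot(is.matrix(edges), radius >= 0, radius == round(radius))
  mode(edges) <- "logical"
  if (radius == 0 || !any(edges)) return(edges)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  closed <- EBImage::closing(edges * 1, brush)
  as.matrix(closed) > 0.5
}

#' Fill enclosed holes and binarize a closed edge map into a slice mask
#'
#' Interior regions fully enclosed by foreground are filled, turning closed
#' outlines into solid cross-sections; open arcs are left as-is.
#'
#' @param closed Logical matrix from [close_edges()].
#' @param z_index Optional slice index carried on the result.
#' @param geometry Optional [voxel_geometry()] carried on the result.
#' @return A `slice_mask`: logical matrix with attributes `z_index` and
#'   `geometry`.
#' @export
fill_and_binarize <- function(closed, z_index = NA_integer_,
                              geometry = NULL) {
  stopifnot(is.matrix(closed))
  mode(closed) <- "logical"
  filled <- if (any(closed))
    as.matrix(EBImage::fillHull(closed * 1)) > 0.5
  else closed
  slice_mask(filled, z_index = z_index, geometry = geometry)
}

#' @rdname fill_and_binarize
#' @param pixels Logical matrix of foreground pixels.
#' @export
slice_mask <- function(pixels, z_index = NA_integer_, geometry = NULL) {
  stopifnot(is.matrix(pixels))
  mode(pixels) <- "logical"
  structure(pixels, z_index = as.integer(z_index),
            geometry = if (!is.null(geometry)) as_geometry(geometry),
            class = c("slice_mask", "matrix"))
}

# 2D 8-connectivity labeling via the 3D labeler on a single-slice volume
.label2d <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- .label3d_cpp(as.logical(array(mask, c(1, ny, nx))), 1L, ny, nx, 26L)
  matrix(lab, ny, nx)
}

#' Remove foreground components touching the image border
#'
#' Any 2D-connected component (8-connectivity) with a pixel on the first or
#' last row or column is removed; such objects are likely truncated.
#' Idempotent.
#'
#' @param mask Logical matrix or `slice_mask`.
#' @return Object of the same kind as `mask`.
#' @export
clear_border_2d <- function(mask) {
  att <- attributes(mask)
  m <- as.matrix(mask)
  mode(m) <- "logical"
  if (any(m)) {
    lab <- .label2d(m)
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    border_labels <- border_labels[border_labels > 0]
    if (length(border_labels)) m[lab %in% border_labels] <- FALSE
  }
  if (inherits(mask, "slice_mask"))
    slice_mask(m, z_index = att$z_index, geometry = att$geometry)
  else m
}

#' Binarize every slice of a stack by in-focus edge detection
#'
#' Applies [detect_focal_edges()], [close_edges()], [fill_and_binarize()]
#' and [clear_border_2d()] to each slice in order. The gradient threshold is
#' a single level pooled over the whole stack (Otsu on all nonzero thinned
#' gradient magnitudes, scaled by `config$edge_threshold`), so slices that
#' contain only defocused content stay empty rather than adapting their
#' threshold downward.
#'
#' @param stack An [image_stack()].
#' @param config A [run_config()].
#' @return List of `slice_mask`, one per slice, with per-slice foreground
#'   fractions in attribute `foreground_fraction`.
#' @export
binarize_stack <- function(stack, config = run_config()) {
  stopifnot(inherits(stack, "image_stack"), inherits(config, "run_config"))
  thinned <- lapply(stack$slices, function(s) {
    g <- .prewitt_gradient(s)
    .nonmax_suppress(g$mag, g$gx, g$gy)
  })
  pos <- unlist(lapply(thinned, function(t) t[t > 0]), use.names = FALSE)
  level <- if (length(pos)) .otsu(pos) * config$edge_threshold else Inf
  masks <- vector("list", length(thinned))
  for (k in seq_along(thinned)) {
    m <- tryCatch({
      edges <- thinned[[k]] > level
      closed <- close_edges(edges, config$close_radius)
      msk <- if (config$fill_holes)
        fill_and_binarize(closed, z_index = k, geometry = stack$geometry)
      else
        slice_mask(closed, z_index = k, geometry = stack$geometry)
      clear_border_2d(msk)
    }, error = function(e)
      stop(sprintf("slice %d: %s", k, conditionMessage(e)), call. = FALSE))
    masks[[k]] <- m
  }
  attr(masks, "foreground_fraction") <-
    vapply(masks, mean, numeric(1))
  masks
}
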