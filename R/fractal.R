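# Box-count fractal dimension in 2D and 3D.
#
# The occupied-box count N(eps) of a fractal object scales as
# N(eps) ~ eps^(-D); D is minus the least-squares slope of ln N vs ln eps.
# D = 3 for a filled cube, 2 for a filled square, 1 for a straight line of
# voxels, and log(20)/log(3) ~ 2.7268 for the Menger sponge.

# resolve a ladder specification against an array: "pow2" = powers of two
# from 1 to the largest power <= the smallest array side
.resolve_ladder <- function(ladder, x) {
  if (is.numeric(ladder)) return(sort(unique(as.integer(ladder))))
  if (identical(ladder, "pow2")) {
    m <- min(dim(x))
    return(2^(0:max(0, floor(log2(m)))))
  }
  stop("eps_ladder must be \"pow2\" or an integer vector")
}

#' Box-count curve of a binary array
#'
#' Partitions the array into an axis-aligned grid of `eps`-sided boxes
#' anchored at index 0 (partial boxes at the far edges included) and counts
#' the boxes containing at least one foreground cell, for every box size in
#' the ladder. 3D input is assumed already isotropic (see
#' [resample_isotropic()]).
#'
#' @param x Logical (or 0/1) array, 2D or 3D — typically a particle's tight
#'   bounding box.
#' @param sizes Integer vector of box side lengths, or `NULL` for the
#'   power-of-two ladder up to the smallest array side.
#' @param pitch Optional micrometers per cell, used to report box sizes in
#'   physical units.
#' @return An object of class `box_count_curve` with `sizes`, `counts`,
#'   `sizes_um` (if `pitch` given), `dimensionality` and
#'   `normalization_length` (set by [normalize_curve()]).
#' @examples
#' cube <- array(TRUE, c(16, 16, 16))
#' box_count(cube)$counts          # (16/eps)^3
#' @export
box_count <- function(x, sizes = NULL, pitch = NULL) {
  stopifnot(is.array(x) || is.matrix(x))
  ndim <- length(dim(x))
  if (!ndim %in% c(2, 3)) stop("x must be a 2D or 3D array")
  mode(x) <- "logical"
  if (!any(x)) stop("empty foreground: no box-count curve definable")
  if (is.null(sizes)) sizes <- .resolve_ladder("pow2", x)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1) || any(sizes > max(dim(x))))
    stop("box sizes must be positive and no larger than the array")
  coords <- which(x, arr.ind = TRUE)   # n x ndim, 1-based
  counts <- vapply(sizes, function(eps) {
    b <- (coords - 1L) %/% eps
    key <- b[, 1]
    mult <- 1
    for (d in 2:ndim) {
      mult <- mult * (dim(x)[d - 1] %/% eps + 1)
      key <- key + b[, d] * mult
    }
    length(unique(key))
  }, numeric(1))
  structure(
    list(sizes = sizes, counts = counts,
         sizes_um = if (!is.null(pitch)) sizes * pitch,
         dimensionality = ndim, normalization_length = NULL),
    class = "box_count_curve"
  )
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat(sprintf("box-count curve (%dD), %d box sizes:\n",
              x$dimensionality, length(x$sizes)))
  print(data.frame(eps = x$sizes, N = x$counts), row.names = FALSE)
  invisible(x)
}

#' @export
plot.box_count_curve <- function(x, ...) {
  graphics::plot(x$sizes, x$counts, log = "xy",
                 xlab = "box size (eps)", ylab = "occupied boxes N",
                 pch = 19, ...)
  fit <- tryCatch(fit_fractal_dimension(x), error = function(e) NULL)
  if (!is.null(fit)) {
    graphics::lines(x$sizes, exp(fit$intercept) * x$sizes^(-fit$dimension),
                    lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("D = %.3f (r2 = %.4f)",
                                      fit$dimension, fit$r2))
  }
  invisible(x)
}

#' Fit the fractal dimension from a box-count curve
#'
#' Ordinary least squares of `ln N` on `ln eps`; the dimension is minus the
#' slope. Local slopes between adjacent ladder points diagnose
#' monofractality: a monofractal object has the same slope at every scale.
#'
#' @param curve A [box_count_curve()].
#' @param fit_range Optional length-2 numeric: inclusive `eps` bounds of the
#'   points used in the fit (e.g. to drop the saturated largest box).
#' @param r2_min,max_local_dev Monofractality thresholds (see
#'   [monofractality_test()]).
#' @return An object of class `fractal_fit`: `dimension`, `intercept`,
#'   `r2`, `local_slopes`, `monofractal_flag`, plus the points used.
#' @export
fit_fractal_dimension <- function(curve, fit_range = NULL,
                                  r2_min = 0.98, max_local_dev = 0.15) {
  stopifnot(inherits(curve, "box_count_curve"))
  eps <- curve$sizes
  N <- curve$counts
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2)
    keep <- eps >= fit_range[1] & eps <= fit_range[2]
    eps <- eps[keep]; N <- N[keep]
  }
  if (length(eps) < 3)
    stop("need at least 3 (eps, N) pairs to fit a dimension")
  lx <- log(eps); ly <- log(N)
  fit <- lm(ly ~ lx)
  slope <- unname(coef(fit)[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot < 1e-300) {
    if (ss_res < 1e-12) 1 else 0   # flat curve (single point object)
  } else 1 - ss_res / ss_tot
  local <- -diff(ly) / diff(lx)
  D <- -slope
  flag <- r2 >= r2_min && (length(local) == 0 ||
                           max(abs(local - D)) <= max_local_dev)
  structure(
    list(dimension = D, intercept = unname(coef(fit)[1]), r2 = r2,
         local_slopes = local, monofractal_flag = flag,
         sizes = eps, counts = N,
         r2_min = r2_min, max_local_dev = max_local_dev),
    class = "fractal_fit"
  )
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("fractal fit: D = %.4f (r2 = %.5f), %d points, %s\n",
              x$dimension, x$r2, length(x$sizes),
              if (x$monofractal_flag) "monofractal" else "not monofractal"))
  invisible(x)
}

#' Monofractality diagnostic
#'
#' An object is monofractal when its box-count curve is linear in log-log
#' space — one dimension across all observed scales. Declared true iff the
#' fit r-squared reaches `r2_min` and no local (adjacent-pair) slope
#' deviates from the fitted dimension by more than `max_local_dev`.
#'
#' @param fit A `fractal_fit`.
#' @param r2_min Minimum r-squared.
#' @param max_local_dev Maximum absolute local-slope deviation.
#' @return Logical.
#' @export
monofractality_test <- function(fit, r2_min = 0.98, max_local_dev = 0.15) {
  stopifnot(inherits(fit, "fractal_fit"))
  fit$r2 >= r2_min && (length(fit$local_slopes) == 0 ||
                       max(abs(fit$local_slopes - fit$dimension)) <=
                         max_local_dev)
}

#' Pixelated-sphere calibration of the box-count resolution bias
#'
#' A perfect sphere has dimension 3, but rasterization and the box-count
#' method produce an artificial surface roughness whose effect grows as
#' particles shrink. Rasterizing solid spheres of increasing radius and
#' running them through the same analysis as real particles quantifies this
#' size-dependent bias.
#'
#' @param radii Integer voxel radii (>= 1).
#' @param sizes Optional explicit box-size ladder (default: power-of-two
#'   ladder per sphere).
#' @return Data frame with `radius`, `voxel_count`, `dimension`, `r2`.
#' @export
sphere_calibration <- function(radii = c(3, 5, 8, 12, 20, 30),
                               sizes = NULL) {
  stopifnot(all(radii >= 1))
  rows <- lapply(radii, function(r) {
    vol <- generate_solid("sphere", size = r)
    arr <- vol$voxels
    curve <- box_count(arr, sizes = sizes)
    fit <- fit_fractal_dimension(curve)
    data.frame(radius = r, voxel_count = sum(arr),
               dimension = fit$dimension, r2 = fit$r2)
  })
  do.call(rbind, rows)
}

#' Resolution-bias correction of a measured dimension
#'
#' Uses the sphere calibration curve: a sphere of the particle's size
#' measures `D_sphere < 3` purely through rasterization, so the corrected
#' dimension is `D + (3 - D_sphere(voxel_count))`, with `D_sphere`
#' log-linearly interpolated in voxel count. Reported alongside, never in
#' place of, the raw dimension. Outside the calibrated range the nearest
#' endpoint is used, with a warning.
#'
#' @param D_measured Measured box-count dimension(s).
#' @param voxel_count Particle size(s) in voxels.
#' @param calibration Data frame from [sphere_calibration()].
#' @return Corrected dimension(s).
#' @export
bias_correct <- function(D_measured, voxel_count, calibration) {
  stopifnot(is.data.frame(calibration),
            all(c("voxel_count", "dimension") %in% names(calibration)),
            length(D_measured) == length(voxel_count))
  rng <- range(calibration$voxel_count)
  if (any(voxel_count < rng[1] | voxel_count > rng[2]))
    warning("voxel_count outside the calibrated range; ",
            "using the nearest calibration endpoint")
  D_sphere <- stats::approx(log(calibration$voxel_count),
                            calibration$dimension,
                            xout = log(voxel_count), rule = 2)$y
  dim_full <- 3
  D_measured + (dim_full - D_sphere)
}

#' Normalize a box-count curve to a reference length
#'
#' Re-expresses box sizes as the dimensionless fraction `eps / L` of a
#' reference image length (micrometers), so curves from instruments with
#' different pixel pitches (e.g. light microscopy vs TEM) share an abscissa.
#' A pure log-shift: counts and the fitted slope are unchanged.
#'
#' @param curve A [box_count_curve()] with physical sizes (`pitch` given at
#'   construction).
#' @param image_length_um Reference length in micrometers.
#' @return A [box_count_curve()] with `sizes` in `(0, 1]` fractions and
#'   `normalization_length` recorded.
#' @export
normalize_curve <- function(curve, image_length_um) {
  stopifnot(inherits(curve, "box_count_curve"), image_length_um > 0)
  if (is.null(curve$sizes_um))
    stop("curve has no physical box sizes; pass `pitch` to box_count()")
  out <- curve
  out$sizes <- curve$sizes_um / image_length_um
  out$normalization_length <- image_length_um
  out
}
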