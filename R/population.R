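# Population-level analysis: size-thresholded group summaries, fractal
# dimension distributions, shear-ranked condition tables, and the Camp
# number shear/aging parameter.

#' Filter a metrics table to the large-particle population
#'
#' Keeps particles strictly larger than `min_voxels`. Restricting the
#' population to the biggest particles minimizes the size-dependent
#' resolution bias of the box-count method (see [sphere_calibration()]).
#' Idempotent.
#'
#' @param metrics Data frame with a `voxel_count` column.
#' @param min_voxels Strict lower voxel-count threshold (default 5000).
#' @return The filtered data frame.
#' @export
filter_population <- function(metrics, min_voxels = 5000) {
  stopifnot(is.data.frame(metrics))
  if (NROW(metrics) == 0) return(metrics)
  metrics[metrics$voxel_count > min_voxels, , drop = FALSE]
}

#' Summarize one condition's particle population
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the fractal
#' dimension, density and surface-to-volume ratio. The SD is the
#' particle-to-particle spread within the sample — a structural
#' distribution, not a measurement error.
#'
#' @param metrics Filtered metrics data frame (n >= 1 rows).
#' @param condition Condition label for the summary.
#' @param threshold_voxels The size threshold that produced `metrics`
#'   (recorded in the summary).
#' @return One-row data frame of class `group_summary`.
#' @export
summarize_group <- function(metrics, condition = "",
                            threshold_voxels = 5000) {
  stopifnot(is.data.frame(metrics))
  if (NROW(metrics) == 0) stop("empty group: nothing to summarize")
  n <- nrow(metrics)
  s <- function(v) if (n >= 2) sd(v) else NA_real_
  out <- data.frame(
    condition = condition,
    n_particles = n,
    mean_D = mean(metrics$fractal_dimension),
    sd_D = s(metrics$fractal_dimension),
    mean_density = mean(metrics$density),
    sd_density = s(metrics$density),
    mean_surface_to_volume = mean(metrics$surface_to_volume_per_um),
    sd_surface_to_volume = s(metrics$surface_to_volume_per_um),
    threshold_voxels = threshold_voxels,
    stringsAsFactors = FALSE
  )
  class(out) <- c("group_summary", class(out))
  out
}

#' Fractal-dimension histogram of a particle population
#'
#' Fixed-width bins spanning `[floor(min D), ceiling(max D)]`; bin counts
#' conserve the number of particles.
#'
#' @param metrics Filtered metrics data frame (n >= 1 rows).
#' @param bin_width Bin width in dimension units (default 0.1).
#' @param condition Condition label carried on the result.
#' @return List of class `dimension_histogram` with `bin_edges`, `counts`,
#'   `condition`.
#' @export
dimension_histogram <- function(metrics, bin_width = 0.1, condition = "") {
  stopifnot(is.data.frame(metrics), bin_width > 0)
  if (NROW(metrics) == 0) stop("empty group: no histogram definable")
  D <- metrics$fractal_dimension
  lo <- floor(min(D)); hi <- ceiling(max(D))
  if (hi <= lo) hi <- lo + 1
  edges <- seq(lo, hi, by = bin_width)
  if (tail(edges, 1) < hi) edges <- c(edges, tail(edges, 1) + bin_width)
  # right-open bins; include.lowest keeps values on the last edge counted
  counts <- hist(D, breaks = edges, plot = FALSE, right = FALSE,
                 include.lowest = TRUE)$counts
  structure(list(bin_edges = edges, counts = counts, condition = condition),
            class = "dimension_histogram")
}

#' @export
print.dimension_histogram <- function(x, ...) {
  cat(sprintf("fractal-dimension histogram ('%s'): %d particles, %d bins\n",
              x$condition, sum(x$counts), length(x$counts)))
  invisible(x)
}

#' Rank condition summaries by expected shear force
#'
#' Arranges group summaries in a user-given order (e.g. increasing expected
#' shear) and flags whether the mean fractal dimension is non-decreasing
#' along it — the trend expected if shear strips loose material until
#' particles reorganize into denser configurations.
#'
#' @param summaries Data frame of stacked [summarize_group()] rows.
#' @param order Character vector: a permutation of the condition names.
#' @return The reordered summary table with attribute `monotone_trend`
#'   (logical).
#' @export
rank_conditions <- function(summaries, order) {
  stopifnot(is.data.frame(summaries), "condition" %in% names(summaries))
  unknown <- setdiff(order, summaries$condition)
  if (length(unknown))
    stop("unknown condition(s) in order: ", paste(unknown, collapse = ", "))
  if (length(order) != nrow(summaries) ||
      anyDuplicated(order) ||
      length(setdiff(summaries$condition, order)))
    stop("order must be a permutation of the condition names")
  out <- summaries[match(order, summaries$condition), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "monotone_trend") <- !is.unsorted(out$mean_D)
  out
}

#' Camp number (velocity-gradient shear/aging parameter)
#'
#' `gamma = sqrt(P / (V * rho * nu))`: the root-mean-square velocity
#' gradient of a stirred volume, relating power input to the shear
#' environment that ages and compacts precipitate flocs.
#'
#' @param P Power input (W).
#' @param V Reactor volume (m^3).
#' @param rho Suspension density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @return Velocity gradient gamma in 1/s.
#' @examples
#' camp_number(P = 2, V = 1e-3, rho = 1000, nu = 1e-6)  # ~1414 1/s
#' @export
camp_number <- function(P, V, rho, nu) {
  vals <- c(P = P, V = V, rho = rho, nu = nu)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Camp number inputs must be positive and finite")
  sqrt(P / (V * rho * nu))
}
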