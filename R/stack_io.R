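#' Construct an image stack
#'
#' An ordered series of equally sized grayscale slices (focal planes at
#' monotonically increasing z) plus the acquisition geometry.
#'
#' @param slices List of numeric matrices (rows = y, columns = x), in
#'   acquisition order, intensities in `[0, 1]` or raw integer counts.
#' @param geometry A [voxel_geometry()].
#' @param name Free-text label for the stack.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, geometry = voxel_geometry(), name = "") {
  stopifnot(is.list(slices), length(slices) >= 1)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share identical height x width")
  structure(
    list(slices = slices, geometry = as_geometry(geometry), name = name),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("image stack '%s': %d slices of %d x %d px, %s\n",
              x$name, length(x$slices), d[1], d[2],
              format(x$geometry)))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$slices)

# collapse an RGB(A) page read by tiff to a grayscale matrix
.to_gray <- function(page) {
  if (is.matrix(page)) {
    attributes(page) <- list(dim = dim(page))   # drop TIFF metadata attrs
    return(page)
  }
  if (length(dim(page)) == 3) {
    nc <- min(dim(page)[3], 3)
    g <- page[, , 1]
    if (nc > 1) for (c in 2:nc) g <- g + page[, , c]
    return(g / nc)
  }
  stop("unsupported TIFF page layout")
}

.check_resolution_tags <- function(path, page, geometry) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || is.null(unit) || !is.numeric(xres) || xres <= 0)
    return(invisible(NULL))
  per_px_um <- switch(as.character(unit),
                      "inch" = 25400 / xres, "2" = 25400 / xres,
                      "cm" = 10000 / xres, "3" = 10000 / xres,
                      NULL)
  if (!is.null(per_px_um) && is.finite(per_px_um) &&
      abs(per_px_um - geometry$dx) > 0.05 * geometry$dx)
    warning(sprintf(
      paste0("TIFF resolution tag of '%s' implies %.4g um/px but the ",
             "supplied geometry says dx = %.4g um/px; using the geometry"),
      basename(path), per_px_um, geometry$dx), call. = FALSE)
  invisible(NULL)
}

#' Read a z-stack from a multi-page TIFF or a directory of TIFFs
#'
#' Slices are ordered by page index for a multi-page file, or by
#' lexicographic filename for a directory of single-page files. Geometry is
#' always taken from the `geometry` argument, never from TIFF metadata; if
#' resolution tags are present and disagree, a warning is issued.
#'
#' @param path A TIFF file or a directory containing `.tif`/`.tiff` files.
#' @param geometry A [voxel_geometry()].
#' @param name Stack label; defaults to the file or directory name.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, geometry = voxel_geometry(), name = NULL) {
  if (is.null(name)) name <- basename(path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0)
      stop("no TIFF files found in directory: ", path)
    slices <- lapply(files, function(f) {
      pages <- tiff::readTIFF(f, all = TRUE, info = TRUE)
      if (length(pages) != 1)
        stop("file in slice directory is not single-page: ", f)
      .check_resolution_tags(f, pages[[1]], geometry)
      .to_gray(pages[[1]])
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(pages) >= 1)
      .check_resolution_tags(path, pages[[1]], geometry)
    slices <- lapply(pages, .to_gray)
  } else {
    stop("path does not exist: ", path)
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slices have mixed dimensions in ", path)
  image_stack(slices, geometry = geometry, name = name)
}

#' Write a stack or binary volume as a multi-page TIFF
#'
#' Grayscale stacks are stored as 32-bit float pages; binary volumes as
#' 8-bit pages with foreground 255 and background 0.
#'
#' @param x An [image_stack()] or [binary_volume()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "image_stack")) {
    pages <- lapply(x$slices, function(s) {
      s[s < 0] <- 0; s[s > 1] <- 1; s
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (inherits(x, "binary_volume")) {
    nz <- dim(x$voxels)[1]
    pages <- lapply(seq_len(nz), function(k) {
      m <- x$voxels[k, , , drop = TRUE]
      storage.mode(m) <- "numeric"
      m
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    stop("x must be an image_stack or binary_volume")
  }
  invisible(path)
}

.metric_columns <- c("label", "voxel_count", "volume_um3", "diameter_um",
                     "density", "surface_area_um2",
                     "surface_to_volume_per_um", "fractal_dimension",
                     "fit_r2", "monofractal_flag", "condition")

#' Write per-particle metrics to CSV
#'
#' Column order is fixed (`label`, `voxel_count`, `volume_um3`,
#' `diameter_um`, `density`, `surface_area_um2`, `surface_to_volume_per_um`,
#' `fractal_dimension`, `fit_r2`, `monofractal_flag`, `condition`) so output
#' files are schema-stable across runs.
#'
#' @param metrics A data frame as returned by [particle_metrics_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (NROW(metrics) == 0) {
    metrics <- as.data.frame(
      setNames(rep(list(logical(0)), length(.metric_columns)),
               .metric_columns))
  } else {
    missing <- setdiff(.metric_columns, names(metrics))
    if (length(missing))
      stop("metrics table lacks columns: ", paste(missing, collapse = ", "))
    metrics <- metrics[, .metric_columns]
  }
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-particle metrics CSV written by [write_metrics()]
#'
#' @param path CSV path.
#' @return A data frame in the canonical column order.
#' @export
read_metrics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.metric_columns, names(df))
  if (length(missing))
    stop("metrics file lacks columns: ", paste(missing, collapse = ", "))
  df$monofractal_flag <- as.logical(df$monofractal_flag)
  df[, .metric_columns]
}
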