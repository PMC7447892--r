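test_that("voxel geometry validates pitches and records anisotropy", {
  g <- voxel_geometry()
  expect_equal(g$dx, 0.092)
  expect_equal(g$dz, 0.198)
  expect_equal(g$anisotropy, 0.198 / 0.092)
  expect_error(voxel_geometry(dx = 0), "positive")
  expect_error(voxel_geometry(dz = -1), "positive")
  expect_error(voxel_geometry(dx = Inf), "positive")
})

test_that("binary volumes round-trip through TIFF exactly", {
  set.seed(11)
  vox <- array(runif(24 * 16 * 20) > 0.6, c(24, 16, 20))
  vol <- binary_volume(vox, voxel_geometry(1, 1, 1))
  path <- tempfile(fileext = ".tif")
  write_stack(vol, path)
  back <- read_stack(path, voxel_geometry(1, 1, 1))
  expect_length(back, 24)
  rec <- stack_masks(lapply(back$slices, function(s) s > 0.5),
                     voxel_geometry(1, 1, 1))
  expect_identical(rec$voxels, vox)

  cube <- binary_volume(array(TRUE, c(8, 8, 8)), voxel_geometry(1, 1, 1))
  write_stack(cube, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 8)
  expect_true(all(vapply(pages, function(p) all(p == 1), logical(1))))

  empty <- binary_volume(array(FALSE, c(4, 6, 6)), voxel_geometry(1, 1, 1))
  write_stack(empty, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_true(all(vapply(pages, function(p) all(p == 0), logical(1))))
})

test_that("grayscale stacks round-trip to float precision", {
  set.seed(7)
  st <- image_stack(replicate(5, matrix(runif(32 * 40), 32, 40),
                              simplify = FALSE),
                    voxel_geometry(), name = "rt")
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, voxel_geometry())
  expect_length(back, 5)
  for (k in 1:5)
    expect_equal(back$slices[[k]], st$slices[[k]], tolerance = 1e-6)
})

test_that("a long multi-page series keeps its slice count and order", {
  slices <- lapply(1:210, function(k) matrix(k / 210, 8, 8))
  st <- image_stack(slices, voxel_geometry())
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, voxel_geometry())
  expect_length(back, 210)
  expect_equal(back$slices[[37]][1, 1], 37 / 210, tolerance = 1e-6)
})

test_that("directory input is read in lexicographic order", {
  dir <- file.path(tempdir(), "slices_test")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  for (k in 1:4)
    tiff::writeTIFF(matrix(k / 10, 12, 12),
                    file.path(dir, sprintf("s%02d.tif", k)),
                    bits.per.sample = 32L)
  st <- read_stack(dir, voxel_geometry())
  expect_length(st, 4)
  expect_equal(st$slices[[2]][1, 1], 0.2, tolerance = 1e-6)

  one <- file.path(tempdir(), "one_slice")
  dir.create(one, showWarnings = FALSE)
  on.exit(unlink(one, recursive = TRUE), add = TRUE)
  tiff::writeTIFF(matrix(0.5, 6, 6), file.path(one, "a.tif"),
                  bits.per.sample = 32L)
  expect_length(read_stack(one, voxel_geometry()), 1)
})

test_that("bad stack inputs raise informative errors", {
  dir <- file.path(tempdir(), "mixed_dims")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  tiff::writeTIFF(matrix(0, 10, 10), file.path(dir, "a.tif"))
  tiff::writeTIFF(matrix(0, 12, 12), file.path(dir, "b.tif"))
  expect_error(read_stack(dir, voxel_geometry()), "mixed dimensions")

  empty <- file.path(tempdir(), "no_tiffs")
  dir.create(empty, showWarnings = FALSE)
  on.exit(unlink(empty, recursive = TRUE), add = TRUE)
  expect_error(read_stack(empty, voxel_geometry()), "no TIFF")
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "exist")
})

test_that("metrics CSV is schema-stable and round-trips", {
  parts <- lapply(1:3, function(l)
    particle(l, cbind(k = 1:(l + 1), j = rep(2L, l + 1), i = rep(2L, l + 1)),
             voxel_geometry(), condition = "fix"))
  tab <- particle_metrics_table(parts)
  path <- tempfile(fileext = ".csv")
  write_metrics(tab, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  expect_match(lines[1], "^\"label\",\"voxel_count\",\"volume_um3\"")

  back <- read_metrics(path)
  expect_identical(names(back), names(tab))
  for (cn in c("volume_um3", "diameter_um", "density"))
    expect_equal(back[[cn]], tab[[cn]], tolerance = 1e-6)

  write_metrics(tab[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("run configuration round-trips through YAML and rejects typos", {
  cfg <- run_config(edge_threshold = 1.3, close_radius = 3,
                    min_voxels = 80, population_min_voxels = 4000)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back[names(back) != "fit_range"],
               cfg[names(cfg) != "fit_range"])
  writeLines("edge_treshold: 2", path)
  expect_error(read_config(path), "unknown configuration")
})

test_that("provenance JSON records config, geometry and seed", {
  path <- tempfile(fileext = ".json")
  write_provenance(run_config(), path, geometry = voxel_geometry(),
                   seed = 42L)
  prov <- jsonlite::read_json(path)
  expect_equal(prov$seed, 42)
  expect_equal(prov$geometry$dz, 0.198)
  expect_equal(prov$config$population_min_voxels, 5000)
  expect_true(nzchar(prov$version))
})
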