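test_that("box counts of exact solids match closed forms", {
  cube <- array(TRUE, c(64, 64, 64))
  c3 <- box_count(cube)
  expect_equal(c3$sizes, 2^(0:6))
  expect_equal(c3$counts, (64 / 2^(0:6))^3)
  expect_equal(c3$counts[1], sum(cube))          # N(1) = voxel count

  single <- array(FALSE, c(9, 9, 9)); single[4, 5, 6] <- TRUE
  cs <- box_count(single, sizes = c(1, 2, 4, 8))
  expect_equal(cs$counts, rep(1, 4))

  sponge <- generate_solid("menger", 3)$voxels
  cm <- box_count(sponge, sizes = c(1, 3, 9, 27))
  expect_equal(cm$counts, c(8000, 400, 20, 1))

  expect_error(box_count(array(FALSE, c(4, 4, 4))), "empty")
  expect_error(box_count(cube, sizes = 128), "box sizes")
})

test_that("N(eps) is non-increasing on arbitrary volumes", {
  set.seed(5)
  for (t in 1:10) {
    vox <- array(runif(18^3) < runif(1, 0.05, 0.6), c(18, 18, 18))
    if (!any(vox)) next
    curve <- box_count(vox, sizes = c(1, 2, 3, 5, 9, 18))
    expect_false(is.unsorted(rev(curve$counts)))
    expect_equal(curve$counts[1], sum(vox))
  }
})

test_that("box counting agrees with the per-box scan oracle", {
  set.seed(23)
  for (t in 1:25) {
    d <- sample(5:32, 3, replace = TRUE)
    vox <- array(runif(prod(d)) < runif(1, 0.05, 0.5), d)
    if (!any(vox)) next
    eps <- sample(1:min(d), 2)
    curve <- box_count(vox, sizes = eps)
    for (j in seq_along(curve$sizes))
      expect_equal(curve$counts[j],
                   oracle_box_count(vox, curve$sizes[j]))
  }
})

test_that("analytic fractal dimensions are recovered exactly", {
  fit3 <- fit_fractal_dimension(box_count(array(TRUE, c(64, 64, 64))))
  expect_equal(fit3$dimension, 3, tolerance = 1e-9)
  expect_equal(fit3$r2, 1, tolerance = 1e-12)

  fit2 <- fit_fractal_dimension(box_count(matrix(TRUE, 256, 256)))
  expect_equal(fit2$dimension, 2, tolerance = 1e-9)

  rod <- array(TRUE, c(1, 1, 256))
  fit1 <- fit_fractal_dimension(box_count(rod, sizes = 2^(0:8)))
  expect_equal(fit1$dimension, 1, tolerance = 1e-9)

  sponge <- generate_solid("menger", 3)$voxels
  fm <- fit_fractal_dimension(box_count(sponge, sizes = c(1, 3, 9, 27)))
  expect_equal(fm$dimension, log(20) / log(3), tolerance = 1e-9)

  short <- box_count(array(TRUE, c(2, 2, 2)))
  expect_error(fit_fractal_dimension(short), "at least 3")
})

test_that("the fit range can exclude saturated ladder points", {
  cube <- array(TRUE, c(64, 64, 64))
  curve <- box_count(cube)
  fit <- fit_fractal_dimension(curve, fit_range = c(1, 16))
  expect_equal(fit$dimension, 3, tolerance = 1e-9)
  expect_length(fit$sizes, 5)
})

test_that("monofractality holds for uniform solids, fails for mixtures", {
  cube_fit <- fit_fractal_dimension(box_count(array(TRUE, c(64, 64, 64))))
  expect_true(monofractality_test(cube_fit))
  expect_true(cube_fit$monofractal_flag)

  # bifractal: solid cube with a long thin rod attached
  vox <- array(FALSE, c(40, 40, 240))
  vox[1:40, 1:40, 1:40] <- TRUE
  vox[20, 20, 41:240] <- TRUE
  bif <- fit_fractal_dimension(box_count(vox, sizes = 2^(0:5)))
  expect_false(monofractality_test(bif))
})

test_that("sphere calibration exposes the small-size resolution bias", {
  cal <- sphere_calibration(c(3, 8, 30))
  expect_equal(names(cal), c("radius", "voxel_count", "dimension", "r2"))
  expect_lt(cal$dimension[1], cal$dimension[3])
  expect_gt(cal$dimension[3], 2.6)
  expect_lt(cal$dimension[1], 2.1)
  # a tiny sphere (7-voxel cross) measures far below 3
  tiny <- sphere_calibration(1, sizes = 1:3)
  expect_lt(tiny$dimension, 2)
})

test_that("bias correction is self-consistent and bounded by calibration", {
  cal <- sphere_calibration(c(3, 8, 30))
  corrected <- bias_correct(cal$dimension, cal$voxel_count, cal)
  expect_equal(corrected, rep(3, 3), tolerance = 1e-9)
  # correction shrinks from the smallest to the largest calibrated size
  corr <- 3 - stats::approx(log(cal$voxel_count), cal$dimension,
                            xout = log(cal$voxel_count), rule = 2)$y
  expect_gt(corr[1], corr[3])
  expect_warning(
    out <- bias_correct(2.5, 10 * max(cal$voxel_count), cal),
    "outside the calibrated range")
  expect_equal(out, 2.5 + 3 - cal$dimension[3], tolerance = 1e-9)
})

test_that("curve normalization rescales the abscissa but not the slope", {
  ball <- generate_solid("sphere", 16)$voxels
  curve <- box_count(ball, pitch = 0.092)
  norm <- normalize_curve(curve, image_length_um = 33 * 0.092)
  expect_lte(max(norm$sizes), 1)
  expect_equal(fit_fractal_dimension(norm)$dimension,
               fit_fractal_dimension(curve)$dimension, tolerance = 1e-12)

  # same physical disk sampled at two pixel pitches overlaps after scaling
  len_um <- 64
  d_coarse <- disk_image(64, 24)            # 1 um per px
  d_fine <- disk_image(128, 48)             # 0.5 um per px
  nc <- normalize_curve(box_count(d_coarse, sizes = c(4, 8, 16),
                                  pitch = 1), len_um)
  nf <- normalize_curve(box_count(d_fine, sizes = c(8, 16, 32),
                                  pitch = 0.5), len_um)
  expect_equal(nc$sizes, nf$sizes)
  expect_equal(nc$counts, nf$counts, tolerance = 0.15)
  expect_error(normalize_curve(box_count(d_coarse), 64), "physical")
})

test_that("the dimension is translation-insensitive on fixtures", {
  ball <- generate_solid("sphere", 12)$voxels
  base <- fit_fractal_dimension(box_count(ball))$dimension
  d <- dim(ball)
  for (sh in list(c(1, 0, 0), c(0, 2, 1), c(2, 2, 2))) {
    padded <- array(FALSE, d + 4L)
    padded[(1:d[1]) + sh[1], (1:d[2]) + sh[2], (1:d[3]) + sh[3]] <- ball
    # same ladder as the unshifted fixture for comparability
    shifted <- fit_fractal_dimension(
      box_count(padded, sizes = 2^(0:4)))$dimension
    expect_lt(abs(shifted - base), 0.05)
  }
})
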