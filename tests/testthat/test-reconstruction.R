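test_that("stacking masks builds a scaled volume in (z, y, x) order", {
  disk <- disk_image(30, 8)
  vol <- stack_masks(replicate(3, disk, simplify = FALSE),
                     voxel_geometry(1, 1, 1))
  expect_equal(dim(vol$voxels), c(3, 30, 30))
  expect_equal(sum(vol$voxels), 3 * sum(disk))
  expect_true(all(vol$voxels[2, , ] == disk))

  empty <- stack_masks(replicate(4, matrix(FALSE, 5, 5), simplify = FALSE),
                       voxel_geometry(1, 1, 1))
  expect_false(any(empty$voxels))

  expect_error(stack_masks(list(matrix(FALSE, 5, 5), matrix(FALSE, 6, 5))),
               "slice 2")
})

test_that("corner-touching cubes split under 6- but not 26-connectivity", {
  vox <- array(FALSE, c(8, 8, 8))
  vox[1:3, 1:3, 1:3] <- TRUE
  vox[4:6, 4:6, 4:6] <- TRUE
  vol <- binary_volume(vox, voxel_geometry(1, 1, 1))
  expect_equal(label_components(vol, 26)$n, 1)
  expect_equal(label_components(vol, 6)$n, 2)
  expect_error(label_components(vol, 8), "connectivity")

  expect_equal(label_components(
    binary_volume(array(FALSE, c(4, 4, 4)), voxel_geometry(1, 1, 1)))$n, 0)

  cube <- label_components(
    binary_volume(array(TRUE, c(64, 64, 64)), voxel_geometry(1, 1, 1)))
  expect_equal(cube$n, 1)
  expect_equal(sum(cube$labels == 1L), 262144)
})

test_that("component labeling agrees with the propagation oracle", {
  set.seed(41)
  for (t in 1:20) {
    d <- sample(4:12, 3, replace = TRUE)
    vox <- array(runif(prod(d)) < runif(1, 0.15, 0.5), d)
    conn <- sample(c(6L, 18L, 26L), 1)
    lab <- label_components(binary_volume(vox, voxel_geometry(1, 1, 1)),
                            conn)
    oracle <- oracle_label3d(vox, conn)
    expect_equal(lab$n, max(oracle))
    if (lab$n > 0) {
      # same partition: cross-tabulation is a permutation matrix
      tab <- table(lab$labels[vox], oracle[vox])
      expect_equal(sum(tab > 0), lab$n)
    }
  }
})

test_that("small-component removal uses the voxel-count threshold", {
  vox <- array(FALSE, c(30, 40, 60))
  vox[2:3, 2:3, 2:4] <- TRUE                       # 12 voxels -> "10" scale
  vox[10:19, 10:34, 10:29] <- TRUE                 # 5000 voxels
  vox[21:28, 2:39, 15:54] <- TRUE                  # 12160 voxels
  lab <- label_components(binary_volume(vox, voxel_geometry(1, 1, 1)))
  expect_equal(lab$n, 3)
  kept <- remove_small(lab, 5000)
  expect_equal(kept$n, 2)
  sizes <- tabulate(kept$labels[kept$labels > 0])
  expect_setequal(sizes, c(5000, 12160))
  expect_equal(remove_small(lab, 0)$n, 3)
  expect_equal(remove_small(lab, 1e6)$n, 0)
})

test_that("border-touching components are removed and labels compacted", {
  vox <- array(FALSE, c(20, 20, 20))
  vox[8:12, 8:12, 8:12] <- TRUE                    # centered, kept
  lab <- label_components(binary_volume(vox, voxel_geometry(1, 1, 1)))
  expect_equal(remove_border_touching(lab)$n, 1)

  vox2 <- vox
  vox2[18:20, 2:5, 2:5] <- TRUE                    # touches last z face
  lab2 <- label_components(binary_volume(vox2, voxel_geometry(1, 1, 1)))
  expect_equal(lab2$n, 2)
  kept <- remove_border_touching(lab2)
  expect_equal(kept$n, 1)
  expect_equal(sort(unique(as.vector(kept$labels))), c(0L, 1L))

  allfg <- label_components(
    binary_volume(array(TRUE, c(6, 6, 6)), voxel_geometry(1, 1, 1)))
  expect_equal(remove_border_touching(allfg)$n, 0)
})

test_that("pillar filter removes constant-footprint z-spanning columns only", {
  nz <- 30
  vox <- array(FALSE, c(nz, 40, 40))
  vox[, 5:9, 5:9] <- TRUE                          # perfect pillar
  sph <- generate_solid("sphere", 5)$voxels        # spans 11/30 slices
  vox <- place_block(vox, sph, c(10, 20, 20))
  # tilted rod spanning all slices with drifting footprint
  for (k in 1:nz) vox[k, 35, min(40, k)] <- TRUE
  lab <- label_components(binary_volume(vox, voxel_geometry(1, 1, 1)))
  expect_equal(lab$n, 3)
  kept <- remove_pillars(lab)
  expect_equal(kept$n, 2)
  sizes <- tabulate(kept$labels[kept$labels > 0])
  expect_true(sum(sph) %in% sizes)                 # sphere kept
  expect_true(nz %in% sizes)                       # tilted rod kept
})

test_that("particle extraction sorts by size and conserves voxels", {
  vox <- array(FALSE, c(15, 25, 25))
  vox[2:4, 2:4, 2:4] <- TRUE
  vox[7:13, 5:14, 5:14] <- TRUE
  vox[2:3, 20:24, 20:23] <- TRUE
  lab <- label_components(binary_volume(vox, voxel_geometry(1, 1, 1)))
  parts <- extract_particles(lab, condition = "testcond")
  expect_length(parts, 3)
  ns <- vapply(parts, function(p) nrow(p$coords), integer(1))
  expect_false(is.unsorted(rev(ns)))
  expect_equal(sum(ns), sum(vox))
  expect_true(all(vapply(parts, function(p) p$condition == "testcond",
                         logical(1))))
  empty <- remove_small(lab, 1e6)
  expect_length(extract_particles(empty), 0)
})

test_that("filters never add voxels and keep labels compact", {
  set.seed(91)
  for (t in 1:5) {
    vox <- array(runif(16 * 20 * 20) < 0.3, c(16, 20, 20))
    lab <- label_components(binary_volume(vox, voxel_geometry(1, 1, 1)))
    before <- sum(lab$labels > 0)
    for (f in list(function(l) remove_small(l, 5),
                   remove_border_touching,
                   remove_pillars)) {
      out <- f(lab)
      expect_lte(sum(out$labels > 0), before)
      if (out$n > 0)
        expect_identical(sort(unique(out$labels[out$labels > 0])),
                         seq_len(out$n))
    }
  }
})

test_that("isotropic resampling replicates slices by round(dz/dx)", {
  disk <- disk_image(21, 7)
  vol <- stack_masks(replicate(5, disk, simplify = FALSE),
                     voxel_geometry(0.092, 0.092, 0.198))
  iso <- resample_isotropic(vol)
  expect_equal(dim(iso$voxels)[1], 10)             # factor round(2.152) = 2
  expect_equal(sum(iso$voxels), 2 * sum(vol$voxels))
  expect_equal(iso$geometry$dz, 0.198 / 2)
  expect_true(all(iso$voxels[1, , ] == iso$voxels[2, , ]))
  expect_true(all(iso$voxels[3, , ] == disk))

  already <- binary_volume(array(TRUE, c(3, 4, 4)), voxel_geometry(1, 1, 1))
  expect_identical(resample_isotropic(already)$voxels, already$voxels)

  down <- binary_volume(array(TRUE, c(3, 4, 4)), voxel_geometry(2, 2, 1))
  expect_warning(out <- resample_isotropic(down), "not supported")
  expect_identical(out$voxels, down$voxels)
})
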