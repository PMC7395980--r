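test_that("analytic mask matches a brute-force ellipsoid predicate", {
  # 8 mm sphere on a 1 mm grid: voxel count equals the brute-force count of
  # grid centers within 8 mm of the nodule center
  p <- phantom_params(grid_shape = c(40L, 40L, 40L), radii = c(8, 8, 8),
                      radial_bumpiness = 0, nodule_center = c(20.5, 20.5, 20.5),
                      seed = 1)
  mask <- analytic_mask(p)
  idx <- which(array(TRUE, p$grid_shape), arr.ind = TRUE)
  d2 <- (idx[, 1] - 20.5)^2 + (idx[, 2] - 20.5)^2 + (idx[, 3] - 20.5)^2
  expect_identical(sum(mask), sum(d2 <= 64))
  expect_identical(as.integer(mask[cbind(idx[, 1], idx[, 2], idx[, 3])]),
                   as.integer(d2 <= 64))
})

test_that("analytic mask handles degenerate radii and anisotropic spacing", {
  # near-zero radii: at most the voxel nearest the center survives
  p <- phantom_params(grid_shape = c(30L, 30L, 30L), radii = c(1e-6, 1e-6, 1e-6),
                      nodule_center = c(15, 15, 15), radial_bumpiness = 0, seed = 1)
  m <- analytic_mask(p)
  expect_lte(sum(m), 1L)
  expect_equal(which(m == 1L, arr.ind = TRUE)[1, ], c(dim1 = 15, dim2 = 15, dim3 = 15))
  # anisotropic spacing shrinks the voxel count along the coarse axis
  pa <- phantom_params(grid_shape = c(30L, 30L, 30L), spacing = c(2, 1, 1),
                       radii = c(4, 4, 4), nodule_center = c(15, 15, 15),
                       radial_bumpiness = 0, seed = 1)
  ma <- analytic_mask(pa)
  idx <- which(ma == 1L, arr.ind = TRUE)
  expect_lte(diff(range(idx[, 1])), 4)   # ~4 mm radius at 2 mm spacing
  expect_gte(diff(range(idx[, 2])), 6)
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(tiny_phantom_params(seed = 11, noise_sigma = 15,
                                            reader_jitter = 0.3,
                                            radial_bumpiness = 0.2))
  b <- generate_phantom(tiny_phantom_params(seed = 11, noise_sigma = 15,
                                            reader_jitter = 0.3,
                                            radial_bumpiness = 0.2))
  expect_identical(a$gt_mask, b$gt_mask)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$annotations, b$annotations)
  c <- generate_phantom(tiny_phantom_params(seed = 12, noise_sigma = 15))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("with zero noise and jitter, rasterized reader contours reproduce the mask", {
  case <- generate_phantom(tiny_phantom_params(seed = 2, radii = c(3, 3, 3)))
  ann1 <- Filter(function(a) a$reader == 1L, case$annotations)
  ras <- consensus_mask(ann1, dim(case$volume$data), readers = 1L)
  expect_identical(ras, case$gt_mask)
  # zero-noise volume is exactly two-valued
  expect_setequal(unique(as.numeric(case$volume$data)),
                  c(case$params$background_intensity, case$params$nodule_intensity))
})

test_that("reader jitter produces distinct contours per reader", {
  case <- generate_phantom(tiny_phantom_params(seed = 3, n_readers = 4L,
                                               reader_jitter = 0.4))
  z <- case$annotations[[1]]$slice
  on_slice <- Filter(function(a) a$slice == z, case$annotations)
  expect_length(on_slice, 4L)
  verts <- lapply(on_slice, `[[`, "vertices")
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(verts[[i]], verts[[j]]))
  # vertex-wise mean polygon differs from each reader's own contour
  mean_poly <- Reduce(`+`, verts) / 4
  for (v in verts) expect_gt(max(abs(v - mean_poly)), 0)
})

test_that("zero contrast leaves only noise between inside and outside", {
  # Monte-Carlo check at fixed seed: with nodule == background intensity the
  # two-sample mean difference of voxel values in/out of the mask is ~ 0
  p <- tiny_phantom_params(seed = 9, radii = c(3, 3, 3), noise_sigma = 10,
                           nodule_intensity = -800, background_intensity = -800)
  case <- generate_phantom(p)
  inside <- case$volume$data[case$gt_mask == 1]
  outside <- case$volume$data[case$gt_mask == 0]
  pooled_se <- sqrt(var(inside) / length(inside) + var(outside) / length(outside))
  expect_lt(abs(mean(inside) - mean(outside)), 4 * pooled_se)
})

test_that("enlarging radii never removes mask voxels (bumpiness field fixed)", {
  for (r in list(c(2, 2, 2), c(2, 3, 2.5), c(3, 3, 3))) {
    p1 <- tiny_phantom_params(seed = 5, radii = r, radial_bumpiness = 0.2,
                              grid_shape = c(34L, 34L, 34L))
    p2 <- tiny_phantom_params(seed = 5, radii = r + 0.7, radial_bumpiness = 0.2,
                              grid_shape = c(34L, 34L, 34L))
    m1 <- analytic_mask(p1); m2 <- analytic_mask(p2)
    expect_true(all(m2[m1 == 1L] == 1L))
  }
})

test_that("gt mask and rasterized noiseless contours agree within a 1-voxel band", {
  case <- generate_phantom(tiny_phantom_params(seed = 6, radii = c(3, 3, 3),
                                               radial_bumpiness = 0.25))
  ras <- consensus_mask(case$annotations, dim(case$volume$data))
  diff_idx <- which(ras != case$gt_mask, arr.ind = TRUE)
  if (nrow(diff_idx) > 0) {
    gt_idx <- which(case$gt_mask == 1L, arr.ind = TRUE)
    for (i in seq_len(nrow(diff_idx))) {
      d <- sqrt(min(rowSums(sweep(gt_idx, 2L, diff_idx[i, ])^2)))
      expect_lte(d, sqrt(3))   # within one voxel diagonally
    }
  }
  expect_lt(sum(ras != case$gt_mask) / max(sum(case$gt_mask), 1), 0.2)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(radii = c(-1, 2, 2)), "radii")
  expect_error(phantom_params(radial_bumpiness = 1), "bumpiness")
  expect_error(phantom_params(n_readers = 0), "n_readers")
  # nodule + 10-voxel pad must fit inside the grid
  expect_error(phantom_params(grid_shape = c(20L, 20L, 20L), radii = c(5, 5, 5)),
               "pad")
})

test_that("phantom round-trips through NIfTI + JSON files", {
  dir <- withr::local_tempdir()
  case <- generate_phantom(tiny_phantom_params(seed = 8, noise_sigma = 7,
                                               reader_jitter = 0.2))
  write_phantom(case, dir)
  vol <- read_volume(file.path(dir, "volume.nii.gz"))
  expect_equal(vol$data, case$volume$data, tolerance = 1e-6)
  expect_equal(vol$spacing, case$volume$spacing)
  ann <- read_annotations(file.path(dir, "annotations.json"))
  expect_length(ann, length(case$annotations))
  expect_equal(ann[[3]]$vertices, case$annotations[[3]]$vertices)
  expect_identical(ann[[3]]$reader, case$annotations[[3]]$reader)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$index_base, 1L)
})
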