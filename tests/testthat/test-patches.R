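test_that("VH patches obey constant, ramp and corner-clamping geometry", {
  dims <- c(20L, 20L, 20L)
  const_cube <- nodule_cube(array(3.5, dims), array(0L, dims), 0L,
                            cbind(0:0, 0:0)[rep(1, 3), ], c(1L, 1L, 1L))
  p <- extract_vh_patch(const_cube, c(10, 10, 10), "axial")
  expect_identical(dim(p), c(30L, 30L))
  expect_true(all(p == 3.5))

  # z-ramp: axial patches constant, sagittal patches ramp along rows
  ramp <- array(rep(seq_len(dims[1]), dims[2] * dims[3]), dims)
  rc <- nodule_cube(ramp, array(0L, dims), 0L, cbind(0, 0)[rep(1, 3), ],
                    c(1L, 1L, 1L))
  ax <- extract_vh_patch(rc, c(7, 10, 10), "axial")
  expect_true(all(ax == 7))
  sag <- extract_vh_patch(rc, c(7, 10, 10), "sagittal")
  expect_true(all(sag == matrix(pmin(pmax((7 - 15):(7 + 14), 1), 20), 30, 30)))
  expect_error(extract_vh_patch(rc, c(7, 10, 10), "oblique"), "invalid view")

  # corner center: clamped-index gather oracle
  arr <- array(rnorm(prod(dims)), dims)
  cc <- nodule_cube(arr, array(0L, dims), 0L, cbind(0, 0)[rep(1, 3), ],
                    c(1L, 1L, 1L))
  got <- extract_vh_patch(cc, c(1, 2, 20), "coronal")   # plane (z, x) at y = 2
  want <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    z <- min(max(1 + (i - 16), 1), 20)
    x <- min(max(20 + (j - 16), 1), 20)
    want[i, j] <- arr[z, 2, x]
  }
  expect_identical(got, want)
  # constant fill instead of replication
  gotc <- extract_vh_patch(cc, c(1, 2, 20), "coronal", fill = "constant",
                           fill_value = -1)
  expect_true(all(gotc[1:15, ] == -1))       # rows before the volume start
  expect_true(all(gotc[, 17:30] == -1))      # columns past the volume end
  expect_identical(gotc[16:30, 1:16], want[16:30, 1:16])
})

test_that("SH patches are binary and follow the mask geometry", {
  dims <- c(40L, 40L, 40L)
  mask <- array(0L, dims)
  mask[, 1:40, 1:40] <- 1L     # everything masked
  cube_all <- nodule_cube(array(0, dims), mask, 0L, cbind(0, 0)[rep(1, 3), ],
                          c(1L, 1L, 1L))
  expect_true(all(extract_sh_patch(cube_all, c(20, 20, 20), "axial") == 1L))

  mask2 <- array(0L, dims)
  mask2[18:22, 18:22, 18:22] <- 1L
  cube2 <- nodule_cube(array(0, dims), mask2, 0L, cbind(0, 0)[rep(1, 3), ],
                       c(1L, 1L, 1L))
  expect_true(all(extract_sh_patch(cube2, c(3, 3, 3), "axial") == 0L))
  # boundary-centered window: pixel sum equals the brute-force window count
  ctr <- c(20, 18, 20)
  for (view in c("axial", "coronal", "sagittal")) {
    p <- extract_sh_patch(cube2, ctr, view)
    expect_true(all(p %in% c(0L, 1L)))
    ax <- switch(view, axial = c(2, 3), coronal = c(1, 3), sagittal = c(1, 2))
    fix <- setdiff(1:3, ax)
    cnt <- 0L
    for (r in -15:14) for (cl in -15:14) {
      idx <- ctr
      idx[ax[1]] <- min(max(ctr[ax[1]] + r, 1), dims[ax[1]])
      idx[ax[2]] <- min(max(ctr[ax[2]] + cl, 1), dims[ax[2]])
      cnt <- cnt + mask2[idx[1], idx[2], idx[3]]
    }
    expect_identical(sum(p), as.integer(cnt))
  }
})

test_that("patch streams are aligned, ordered and label-consistent", {
  tc <- tiny_cube(seed = 5, radii = c(3, 3, 3))
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(10, seed = 2))
  st <- build_patch_streams(tc$cube, ctr)
  expect_s3_class(st, "patch_streams")
  expect_named(st$streams, c("axial_vh", "axial_sh", "coronal_vh", "coronal_sh",
                             "sagittal_vh", "sagittal_sh"))
  n <- nrow(ctr)
  for (s in st$streams) expect_identical(dim(s), c(30L, 30L, n))
  expect_identical(st$labels, ctr$label)

  # one center -> 6 patches, each reproducing the direct extraction
  one <- build_patch_streams(tc$cube, ctr[3, , drop = FALSE])
  expect_identical(dim(one$streams$coronal_vh)[3], 1L)
  expect_identical(one$streams$coronal_vh[, , 1],
                   extract_vh_patch(tc$cube, unlist(ctr[3, c("z", "y", "x")]),
                                    "coronal"))
  expect_equal(one$streams$sagittal_sh[, , 1],
               extract_sh_patch(tc$cube, unlist(ctr[3, c("z", "y", "x")]),
                                "sagittal") + 0)

  # view consistency: all views share the center voxel value at the midpoint
  for (i in seq_len(n)) {
    v <- tc$cube$data[ctr$z[i], ctr$y[i], ctr$x[i]]
    expect_equal(st$streams$axial_vh[16, 16, i], v)
    expect_equal(st$streams$coronal_vh[16, 16, i], v)
    expect_equal(st$streams$sagittal_vh[16, 16, i], v)
    m <- as.numeric(tc$cube$mask[ctr$z[i], ctr$y[i], ctr$x[i]])
    expect_equal(st$streams$axial_sh[16, 16, i], m)
    expect_equal(st$streams$coronal_sh[16, 16, i], m)
    expect_equal(st$streams$sagittal_sh[16, 16, i], m)
  }

  # SH strictly binary; VH range inside the cube intensity range
  expect_true(all(st$streams$axial_sh %in% c(0, 1)))
  expect_gte(min(st$streams$coronal_vh), min(tc$cube$data))
  expect_lte(max(st$streams$coronal_vh), max(tc$cube$data))
})

test_that("stream ordering is equivariant under center permutation", {
  tc <- tiny_cube(seed = 5)
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(8, seed = 2))
  st <- build_patch_streams(tc$cube, ctr)
  perm <- rev(seq_len(nrow(ctr)))
  stp <- build_patch_streams(tc$cube, ctr[perm, ])
  for (nm in names(st$streams))
    expect_identical(stp$streams[[nm]], st$streams[[nm]][, , perm])
  expect_identical(stp$labels, st$labels[perm])
})

test_that("empty center tables give empty aligned streams", {
  tc <- tiny_cube(seed = 5)
  st <- build_patch_streams(tc$cube, data.frame(z = integer(), y = integer(),
                                                x = integer(), label = integer()))
  for (s in st$streams) expect_identical(dim(s)[3], 0L)
  expect_length(st$labels, 0L)
})

test_that("min-max VH normalization maps the cube range to [0, 1]", {
  tc <- tiny_cube(seed = 5, noise_sigma = 10)
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(6, seed = 2))
  st <- build_patch_streams(tc$cube, ctr, vh_normalize = "minmax")
  expect_gte(min(st$streams$axial_vh), 0)
  expect_lte(max(st$streams$axial_vh), 1)
  rng <- range(tc$cube$data)
  raw <- build_patch_streams(tc$cube, ctr)
  expect_equal(st$streams$axial_vh,
               (raw$streams$axial_vh - rng[1]) / diff(rng))
})
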