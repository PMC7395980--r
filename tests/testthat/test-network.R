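test_that("submodel stage shapes match the reference architecture", {
  shp <- sir_stage_shapes(net_config())
  expect_identical(shp$input, c(30L, 30L, 1L))
  expect_identical(shp$c1, c(30L, 30L, 32L))
  expect_identical(shp$p2, c(15L, 15L, 32L))
  expect_identical(shp$block1, c(15L, 15L, 32L))
  expect_identical(shp$secondary, c(15L, 15L, 32L))
  expect_identical(shp$concat, c(15L, 15L, 64L))
  expect_identical(shp$p3, c(8L, 8L, 64L))
  expect_identical(shp$c4, c(8L, 8L, 128L))
  expect_identical(shp$block2, c(8L, 8L, 128L))
  expect_identical(shp$p5, c(8L, 8L, 128L))
  expect_identical(shp$flatten, 8192L)
  expect_identical(shp$f7, 256L)
  expect_identical(shp$f8, 256L)
  expect_identical(shp$fusion_input, 1536L)
  expect_identical(shp$fusion, 256L)
  expect_identical(shp$output, 1L)
})

test_that("ablation variants drop the secondary path and residual blocks", {
  icnn <- sir_stage_shapes(net_config(variant = "MV-I-CNN"))
  expect_null(icnn$secondary)
  expect_identical(icnn$concat, c(15L, 15L, 32L))   # no concatenation widening
  expect_identical(icnn$c4, c(8L, 8L, 128L))
  cnn <- sir_stage_shapes(net_config(variant = "MV-CNN"))
  expect_null(cnn$secondary)
  expect_identical(cnn$block1, c(15L, 15L, 32L))
  expect_identical(cnn$block2, c(8L, 8L, 128L))
  # parameter nesting: MV-CNN < MV-I-CNN < MV-SIR for the same configuration
  n_cnn <- count_parameters(net_config(variant = "MV-CNN"))
  n_icnn <- count_parameters(net_config(variant = "MV-I-CNN"))
  n_sir <- count_parameters(net_config(variant = "MV-SIR"))
  expect_lt(n_cnn, n_icnn)
  expect_lt(n_icnn, n_sir)
})

test_that("net_config rejects widths that break the identity skip", {
  expect_error(net_config(rb1_widths = c(32L, 32L, 16L)), "addable")
  expect_error(net_config(stem_channels = 16L), "addable")
  expect_error(net_config(rb2_widths = c(128L, 128L, 64L)), "addable")
})

test_that("residual block reduces to ReLU(input) with a zero main path", {
  withr::local_seed(1)
  C <- 8L; H <- 5L; W <- 5L
  x <- array(rnorm(H * W * C), c(H, W, C))
  zw <- list(w1 = matrix(0, C, C), b1 = rep(0, C),
             w2 = matrix(0, 9 * C, C), b2 = rep(0, C),
             w3 = matrix(0, C, C), b3 = rep(0, C))
  out <- residual_block(x, zw)
  expect_equal(out, array(pmax(x, 0), dim(x)), tolerance = 1e-6)

  # additivity: output = ReLU(main path + skip); with a bias-only main path
  # the shift is visible through the skip
  bw <- zw; bw$b3 <- rep(0.5, C)
  expect_equal(residual_block(x, bw), array(pmax(x + 0.5, 0), dim(x)),
               tolerance = 1e-6)

  # shape preservation on the deep stage size
  x2 <- array(rnorm(15 * 15 * 32), c(15, 15, 32))
  w2 <- list(w1 = matrix(rnorm(32 * 32, sd = 0.1), 32, 32), b1 = rep(0, 32),
             w2 = matrix(rnorm(288 * 32, sd = 0.05), 288, 32), b2 = rep(0, 32),
             w3 = matrix(rnorm(32 * 32, sd = 0.1), 32, 32), b3 = rep(0, 32))
  expect_identical(dim(residual_block(x2, w2)), c(15L, 15L, 32L))
  # channel mismatch is a construction error
  bad <- w2; bad$w3 <- matrix(0, 32, 16)
  expect_error(residual_block(x2, bad), "identity skip")
})

test_that("sigmoid and binary cross-entropy match their closed forms", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(c(-700, 700)), c(0, 1), tolerance = 1e-12)
  z <- seq(-5, 5, by = 0.5)
  expect_equal(sigmoid(z), 1 / (1 + exp(-z)))

  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0.5), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(0, 1), c(0, 1)), 1e-5)   # near-perfect prediction
  expect_error(bce_loss(1, 1.2), "outside")
  expect_error(bce_loss(c(1, 0), 0.5), "length")

  # naive one-term-at-a-time summation oracle on random batches
  withr::local_seed(3)
  for (rep in 1:5) {
    y <- rbinom(40, 1, 0.5)
    p <- runif(40)
    acc <- 0
    for (i in seq_along(y)) {
      pi <- min(max(p[i], 1e-7), 1 - 1e-7)
      acc <- acc - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
    }
    expect_equal(bce_loss(y, p), acc / length(y), tolerance = 1e-12)
  }
})

test_that("model probabilities are bounded and centered for a zero head", {
  tc <- tiny_cube(seed = 5, radii = c(3, 3, 3))
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(8, seed = 2))
  st <- build_patch_streams(tc$cube, ctr, vh_normalize = "minmax")
  net <- tiny_net_config()
  m <- mvsir(st, net, train_config(epochs = 1, batch_size = 8, seed = 1))
  p <- predict(m, st)
  expect_true(all(p > 0 & p < 1))
  # zeroed output layer forces probability exactly 0.5 (sigmoid(0))
  m0 <- m
  m0$weights$out_w[] <- 0
  m0$weights$out_b[] <- 0
  expect_true(all(predict(m0, st) == 0.5))
})

test_that("training fits a small separable set and is seed-sensitive", {
  tc <- tiny_cube(seed = 5, radii = c(3, 3, 3))
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(12, seed = 2))
  st <- build_patch_streams(tc$cube, ctr, vh_normalize = "minmax")
  net <- tiny_net_config()
  m <- mvsir(st, net, train_config(epochs = 25, batch_size = 16,
                                   learning_rate = 3e-3, seed = 4))
  expect_identical(nrow(m$curve), 25L)
  expect_named(m$curve, c("epoch", "loss", "acc", "val_loss", "val_acc"))
  # overfit-a-tiny-set oracle: the moving average of the loss must drop well
  # below its starting level
  first <- mean(m$curve$loss[1:3])
  last <- mean(m$curve$loss[23:25])
  expect_lt(last, first * 0.5)
  expect_gt(m$curve$acc[25], 0.9)

  m2 <- mvsir(st, net, train_config(epochs = 1, batch_size = 16, seed = 5))
  expect_false(identical(m2$weights$fu_w, m$weights$fu_w))

  # single-class streams are rejected
  st_pos <- st
  st_pos$labels <- rep(1L, length(st$labels))
  expect_error(mvsir(st_pos, net, train_config(seed = 1)), "single class")
})

test_that("training smoke contract: one epoch emits one curve row", {
  tc <- tiny_cube(seed = 5)
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(4, seed = 2))
  st <- build_patch_streams(tc$cube, ctr)
  m <- mvsir(st, tiny_net_config(), train_config(epochs = 1, batch_size = 8,
                                                 seed = 1))
  expect_identical(nrow(m$curve), 1L)
  expect_true(is.finite(m$curve$loss))
  expect_s3_class(m, "mvsir")
  expect_output(print(m), "voxel classifier")
})

test_that("fitted models round-trip through the checkpoint format", {
  tc <- tiny_cube(seed = 5)
  ctr <- sample_balanced_centers(tc$cube, sampling_plan(4, seed = 2))
  st <- build_patch_streams(tc$cube, ctr)
  m <- mvsir(st, tiny_net_config(), train_config(epochs = 1, batch_size = 8,
                                                 seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_mvsir(m, path)
  back <- load_mvsir(path)
  expect_equal(predict(back, st), predict(m, st))
  fp <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(fp$variant, "MV-SIR")
  expect_equal(fp$n_params, count_parameters(m))
})
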