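test_that("overlap metrics match closed forms and conventions", {
  m <- array(0L, c(6, 6, 6)); m[2:3, 2:3, 2:3] <- 1L
  ov <- overlap_metrics(m, m)
  expect_identical(c(ov$dice, ov$ppv, ov$sen), c(1, 1, 1))

  # |S| = 4, |G| = 4, |S ∩ G| = 2 -> all three metrics 0.5
  s <- array(0L, c(4, 4, 4)); g <- array(0L, c(4, 4, 4))
  s[1, 1, 1:4] <- 1L; g[1, 1, 3:4] <- 1L; g[2, 2, 1:2] <- 1L
  ov <- overlap_metrics(s, g)
  expect_identical(c(ov$dice, ov$ppv, ov$sen), c(0.5, 0.5, 0.5))

  # conventions: both empty -> dice 1; empty segmentation -> ppv 0 + flag
  e <- array(0L, c(3, 3, 3))
  expect_identical(overlap_metrics(e, e)$dice, 1)
  ov0 <- overlap_metrics(e, g <- {g <- e; g[1, 1, 1] <- 1L; g})
  expect_identical(ov0$ppv, 0)
  expect_true(ov0$empty_seg)
  expect_error(overlap_metrics(array(0L, c(2, 2, 2)), e), "shape")
})

test_that("overlap metrics equal a per-voxel counting oracle on random masks", {
  withr::local_seed(11)
  for (rep in 1:100) {
    s <- random_mask(); g <- random_mask()
    ov <- overlap_metrics(s, g)
    inter <- 0L; ns <- 0L; ng <- 0L
    for (i in seq_along(s)) {
      ns <- ns + (s[i] == 1L); ng <- ng + (g[i] == 1L)
      inter <- inter + (s[i] == 1L && g[i] == 1L)
    }
    expect_equal(ov$dice, 2 * inter / (ns + ng), tolerance = 1e-12)
    expect_equal(ov$ppv, inter / ns, tolerance = 1e-12)
    expect_equal(ov$sen, inter / ng, tolerance = 1e-12)
    # symmetry: dice(S,G) = dice(G,S), ppv(S,G) = sen(G,S)
    rev <- overlap_metrics(g, s)
    expect_identical(rev$dice, ov$dice)
    expect_identical(rev$sen, ov$ppv)
  }
})

test_that("surface extraction finds face-exposed voxels", {
  m <- array(0L, c(7, 7, 7))
  m[4, 4, 4] <- 1L
  expect_identical(nrow(surface_points(m)), 1L)   # singleton

  m333 <- array(0L, c(7, 7, 7)); m333[3:5, 3:5, 3:5] <- 1L
  sp <- surface_points(m333)
  expect_identical(nrow(sp), 26L)                 # all but the center voxel
  expect_false(any(sp[, 1] == 3 & sp[, 2] == 3 & sp[, 3] == 3))  # center (mm) absent

  m555 <- array(0L, c(9, 9, 9)); m555[3:7, 3:7, 3:7] <- 1L
  expect_identical(nrow(surface_points(m555)), 125L - 27L)  # hollow interior

  # array border counts as outside: a mask filling the array is all surface
  # on its faces only
  full <- array(1L, c(3, 3, 3))
  expect_identical(nrow(surface_points(full)), 26L)
  expect_error(surface_points(array(0L, c(3, 3, 3))), "empty")

  # spacing scales coordinates into mm
  sp2 <- surface_points(m, spacing = c(2, 1, 0.5))
  expect_equal(sp2[1, ], c(6, 3, 1.5), ignore_attr = TRUE)
})

test_that("hausdorff and average surface distance match brute-force oracles", {
  expect_identical(hausdorff_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  expect_identical(average_surface_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  X <- rbind(c(1, 1, 1), c(2, 2, 2))
  expect_identical(hausdorff_distance(X, X), 0)
  expect_identical(average_surface_distance(X, X), 0)
  expect_error(hausdorff_distance(X[0, , drop = FALSE], X), "empty")

  withr::local_seed(12)
  for (rep in 1:20) {
    X <- matrix(runif(3 * sample(2:12, 1), -5, 5), ncol = 3)
    Y <- matrix(runif(3 * sample(2:12, 1), -5, 5), ncol = 3)
    # O(|X||Y|) double-loop oracle
    dxy <- apply(X, 1, function(x) min(apply(Y, 1, function(y) sqrt(sum((x - y)^2)))))
    dyx <- apply(Y, 1, function(y) min(apply(X, 1, function(x) sqrt(sum((x - y)^2)))))
    expect_equal(hausdorff_distance(X, Y), max(max(dxy), max(dyx)),
                 tolerance = 1e-12)
    expect_equal(average_surface_distance(X, Y), 0.5 * (mean(dxy) + mean(dyx)),
                 tolerance = 1e-12)
    # ordering and symmetry
    expect_lte(average_surface_distance(X, Y), hausdorff_distance(X, Y))
    expect_equal(hausdorff_distance(Y, X), hausdorff_distance(X, Y))
  }
})

test_that("surface distances are translation-invariant and scale with spacing", {
  withr::local_seed(13)
  s <- random_mask(c(10, 10, 10), 0.2); g <- random_mask(c(10, 10, 10), 0.2)
  base <- surface_distance_metrics(s, g)
  # identical shift of both masks
  sh <- function(m) { out <- array(0L, c(12, 12, 12)); out[2:11, 2:11, 2:11] <- m; out }
  shifted <- surface_distance_metrics(sh(s), sh(g))
  expect_equal(shifted$hsd, base$hsd, tolerance = 1e-12)
  expect_equal(shifted$asd, base$asd, tolerance = 1e-12)
  # doubling the spacing doubles every distance
  doubled <- surface_distance_metrics(s, g, spacing = c(2, 2, 2))
  expect_equal(doubled$hsd, 2 * base$hsd, tolerance = 1e-12)
  expect_equal(doubled$asd, 2 * base$asd, tolerance = 1e-12)
})

test_that("ROC analysis finds perfect separation and matches a trapezoid oracle", {
  conf <- c(rep(0.9, 20), rep(0.1, 30))
  truth <- c(rep(1, 20), rep(0, 30))
  roc <- roc_curve(conf, truth)
  expect_identical(roc$auc, 1)
  opt <- roc$optimal_index
  expect_identical(c(roc$fpr[opt], roc$tpr[opt]), c(0, 1))   # corner reached
  expect_identical(roc$optimal_threshold, 0.9)

  # labels + small noise: AUC ~ 1 against an independent trapezoid oracle
  withr::local_seed(14)
  y <- rbinom(300, 1, 0.4)
  p <- pmin(pmax(y + rnorm(300, sd = 0.1), 0), 1)
  roc2 <- roc_curve(p, y)
  expect_gt(roc2$auc, 0.99)
  if (requireNamespace("pROC", quietly = TRUE)) {
    oracle <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                             direction = "<")))
    expect_equal(roc2$auc, oracle, tolerance = 1e-10)
  }

  # label-independent confidences: AUC ~ 0.5 within Monte-Carlo tolerance
  p3 <- runif(4000); y3 <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_curve(p3, y3)$auc - 0.5), 0.05)
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC curves are monotone and ties pick the lower threshold", {
  withr::local_seed(15)
  p <- runif(200); y <- rbinom(200, 1, 0.5)
  roc <- roc_curve(p, y)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  # a duplicated optimum: equal distances at two thresholds -> lower wins
  conf <- c(0.9, 0.8, 0.3, 0.2)
  y2 <- c(1, 0, 1, 0)
  roc2 <- roc_curve(conf, y2)
  d <- sqrt(roc2$fpr^2 + (1 - roc2$tpr)^2)
  cand <- which(d == min(d))
  expect_identical(roc2$optimal_threshold, min(roc2$thresholds[cand]))
})

test_that("evaluate_segmentation assembles the five-metric report", {
  s <- array(0L, c(8, 8, 8)); s[3:5, 3:5, 3:5] <- 1L
  g <- array(0L, c(8, 8, 8)); g[3:5, 3:5, 4:6] <- 1L
  rep <- evaluate_segmentation(s, g, spacing = c(1, 1, 1))
  expect_named(rep, c("dice", "ppv", "sen", "hsd", "asd"))
  expect_equal(rep$dice, 2 * 18 / 54)
  expect_identical(rep$hsd, 1)   # one-voxel shift of a cube
  expect_true(rep$asd > 0 && rep$asd < 1)
})
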