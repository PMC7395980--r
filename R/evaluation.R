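#' Volume-overlap metrics: Dice, PPV, sensitivity
#'
#' `dice = 2|S∩G| / (|S|+|G|)`, `ppv = |S∩G| / |S|`, `sen = |S∩G| / |G|`
#' between a segmentation mask `S` and a ground-truth mask `G` of equal
#' shape. Conventions: two empty masks have Dice 1; an empty segmentation
#' has PPV reported as 0 with `empty_seg = TRUE` flagged (keeps batch
#' evaluation total); an empty ground truth likewise flags `empty_gt`.
#'
#' @param seg,gt 0/1 arrays of equal shape.
#' @return List with `dice`, `ppv`, `sen`, `empty_seg`, `empty_gt`.
#' @export
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- 1L
#' overlap_metrics(m, m)$dice   # 1
overlap_metrics <- function(seg, gt) {
  if (!identical(dim(seg), dim(gt)))
    stop_config("overlap_metrics: shape mismatch")
  s <- sum(seg != 0); g <- sum(gt != 0)
  i <- sum(seg != 0 & gt != 0)
  list(dice = if (s + g == 0) 1 else 2 * i / (s + g),
       ppv = if (s == 0) 0 else i / s,
       sen = if (g == 0) 0 else i / g,
       empty_seg = s == 0, empty_gt = g == 0)
}

#' Surface points of a binary mask
#'
#' A mask voxel is a surface voxel when at least one of its six
#' face-neighbors is outside the mask (the array border counts as outside).
#' Returned points are the voxel centers in physical mm (spacing applied).
#'
#' @param mask Nonempty 0/1 array.
#' @param spacing Voxel spacing in mm `(z, y, x)`.
#' @return Numeric `n x 3` matrix of surface-point coordinates (mm).
#' @export
surface_points <- function(mask, spacing = c(1, 1, 1)) {
  if (sum(mask != 0) == 0L) stop_config("surface_points: empty mask")
  d <- dim(mask)
  m <- array(mask != 0, d)
  interior <- array(TRUE, d)
  shift_ok <- function(axis, by) {
    # neighbor inside the mask? border -> FALSE
    out <- array(FALSE, d)
    if (axis == 1L) {
      if (by == 1L) out[1:(d[1] - 1), , ] <- m[2:d[1], , ]
      else out[2:d[1], , ] <- m[1:(d[1] - 1), , ]
    } else if (axis == 2L) {
      if (by == 1L) out[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
      else out[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
    } else {
      if (by == 1L) out[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
      else out[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
    }
    out
  }
  for (axis in 1:3) for (by in c(1L, -1L))
    interior <- interior & shift_ok(axis, by)
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE)
  index_to_mm(idx, spacing)
}

# all-pairs directed minimal distances from each row of X to the set Y
min_dists <- function(X, Y) {
  # chunked squared-distance matrix via the (x - y)^2 expansion
  nx <- nrow(X)
  out <- numeric(nx)
  y2 <- rowSums(Y^2)
  chunk <- max(1L, floor(2e7 / nrow(Y)))
  for (lo in seq(1L, nx, by = chunk)) {
    hi <- min(lo + chunk - 1L, nx)
    Xc <- X[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(Xc^2), y2, `+`) - 2 * Xc %*% t(Y)
    out[lo:hi] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Hausdorff distance between two point sets
#'
#' `max(sup_x inf_y d(x,y), sup_y inf_x d(x,y))` with Euclidean `d`; the
#' symmetric worst-case surface disagreement, in the units of the inputs
#' (mm when fed [surface_points()]).
#'
#' @param X,Y Nonempty `n x 3` point matrices.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' hausdorff_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))   # 5
hausdorff_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L)
    stop_config("hausdorff_distance: empty point set")
  max(max(min_dists(X, Y)), max(min_dists(Y, X)))
}

#' Average symmetric surface distance between two point sets
#'
#' Half-sum of the two directed mean minimal distances:
#' `0.5 * (mean_x min_y d(x,y) + mean_y min_x d(x,y))`. Always bounded above
#' by the Hausdorff distance.
#'
#' @inheritParams hausdorff_distance
#' @return Nonnegative scalar.
#' @export
average_surface_distance <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L)
    stop_config("average_surface_distance: empty point set")
  0.5 * (mean(min_dists(X, Y)) + mean(min_dists(Y, X)))
}

#' Surface-distance metrics between two masks
#'
#' Extracts both masks' surface points and reports the Hausdorff (HSD) and
#' average symmetric surface distance (ASD) in mm. Sub-voxel ASD values are
#' meaningful because distances are physical.
#'
#' @param seg,gt Nonempty 0/1 arrays of equal shape.
#' @param spacing Voxel spacing in mm.
#' @return List with `hsd` and `asd` (mm).
#' @export
surface_distance_metrics <- function(seg, gt, spacing = c(1, 1, 1)) {
  if (!identical(dim(seg), dim(gt)))
    stop_config("surface_distance_metrics: shape mismatch")
  S <- surface_points(seg, spacing)
  G <- surface_points(gt, spacing)
  list(hsd = hausdorff_distance(S, G), asd = average_surface_distance(S, G))
}

#' ROC curve and closest-to-upper-left optimal threshold
#'
#' Sweeps thresholds over the observed confidences, computing the false
#' positive rate (FPR) and true positive rate (TPR) of `confidence >=
#' threshold` against the 0/1 truth. The optimal threshold minimizes the
#' Euclidean distance to the upper-left corner, `sqrt(FPR^2 + (1-TPR)^2)`,
#' with ties resolved toward the lower threshold; AUC is computed by the
#' trapezoidal rule.
#'
#' @param confidence Numeric confidences (array or vector).
#' @param truth 0/1 labels of the same length/shape; both classes must be
#'   present.
#' @return An object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `optimal_threshold`, `optimal_index`.
#' @export
roc_curve <- function(confidence, truth) {
  conf <- as.numeric(confidence)
  y <- as.integer(as.numeric(truth) != 0)
  keep <- !is.na(conf)
  conf <- conf[keep]; y <- y[keep]
  if (length(unique(y)) < 2L)
    stop_config("roc_curve: truth must contain both classes")
  ord <- order(conf, decreasing = TRUE)
  conf_s <- conf[ord]; y_s <- y[ord]
  P <- sum(y_s); N <- length(y_s) - P
  tp <- cumsum(y_s); fp <- cumsum(1 - y_s)
  last <- !duplicated(conf_s, fromLast = TRUE)       # one point per threshold
  thr <- conf_s[last]
  tpr <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  thr <- c(Inf, thr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  dist <- sqrt(fpr^2 + (1 - tpr)^2)
  cand <- which(dist == min(dist))
  opt <- cand[length(cand)]   # largest index = lowest threshold among ties
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 optimal_threshold = thr[opt], optimal_index = opt),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.4f, optimal threshold %.4f (FPR %.3f, TPR %.3f)\n",
              x$auc, x$optimal_threshold, x$fpr[x$optimal_index],
              x$tpr[x$optimal_index]))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::points(x$fpr[x$optimal_index], x$tpr[x$optimal_index], pch = 19,
                   col = "red")
  invisible(x)
}

#' ROC-optimal threshold of a prediction volume against a reference mask
#'
#' @param pred A [predict_cube()] result.
#' @param gt 0/1 reference array of the same shape.
#' @return A [roc_curve()] computed on the evaluated voxels.
#' @export
roc_optimal_threshold <- function(pred, gt) {
  stopifnot(inherits(pred, "prediction_volume"))
  if (!identical(dim(pred$confidence), dim(gt)))
    stop_config("roc_optimal_threshold: shape mismatch")
  roc_curve(pred$confidence, gt)
}

#' Full segmentation evaluation report
#'
#' One row of the five standard metrics — Dice, PPV, sensitivity, HSD and
#' ASD — for a segmentation against a reference mask.
#'
#' @param seg,gt 0/1 arrays of equal shape.
#' @param spacing Voxel spacing in mm.
#' @return A one-row `data.frame` with columns `dice, ppv, sen, hsd, asd`.
#' @export
evaluate_segmentation <- function(seg, gt, spacing = c(1, 1, 1)) {
  ov <- overlap_metrics(seg, gt)
  sd <- if (sum(seg != 0) > 0 && sum(gt != 0) > 0)
    surface_distance_metrics(seg, gt, spacing)
  else list(hsd = NA_real_, asd = NA_real_)
  data.frame(dice = ov$dice, ppv = ov$ppv, sen = ov$sen,
             hsd = sd$hsd, asd = sd$asd)
}
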