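#' Per-voxel nodule probabilities for a model over centers
#'
#' Internal dispatch point used by [predict_cube()]: given a cube and a
#' table of voxel centers, returns one probability per center. Methods exist
#' for fitted [mvsir()] models and for the two diagnostic stubs
#' [constant_model()] and [oracle_model()].
#'
#' @param model The classifier.
#' @param cube A [nodule_cube()].
#' @param centers `data.frame` with columns `z, y, x`.
#' @param ... Method-specific options.
#' @return Numeric probabilities, one per center row.
#' @keywords internal
#' @export
predict_voxels <- function(model, cube, centers, ...) UseMethod("predict_voxels")

#' @rdname predict_voxels
#' @param chunk Centers scored per forward chunk.
#' @param vh_normalize VH normalization applied before patch extraction; use
#'   the same setting the model was trained with.
#' @param fill,fill_value Out-of-bounds patch fill, see [extract_vh_patch()].
#' @export
predict_voxels.mvsir <- function(model, cube, centers, chunk = 2048L,
                                 vh_normalize = c("none", "minmax"),
                                 fill = c("replicate", "constant"),
                                 fill_value = 0, ...) {
  vh_normalize <- match.arg(vh_normalize)
  fill <- match.arg(fill)
  size <- model$net_config$patch_size
  n <- nrow(centers)
  probs <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    sub <- centers[lo:hi, , drop = FALSE]
    sub$label <- 0L
    streams <- build_patch_streams(cube, sub, size = size, fill = fill,
                                   fill_value = fill_value,
                                   vh_normalize = vh_normalize)
    probs[lo:hi] <- predict(model, streams)
  }
  probs
}

#' Diagnostic stub classifiers
#'
#' `constant_model(p)` scores every voxel with the same probability;
#' `oracle_model(reference)` returns the reference mask's value at each
#' voxel. Both plug into [predict_cube()] in place of a fitted model, which
#' makes the reassembly/thresholding path testable independently of
#' learning: the oracle stub must reproduce its reference exactly (Dice 1).
#'
#' @param p Constant probability in `[0, 1]`.
#' @param reference 0/1 array aligned to the cube to be predicted.
#' @return A classifier usable with [predict_cube()].
#' @export
constant_model <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  structure(list(p = p), class = c("mvsir_constant", "mvsir_stub"))
}

#' @rdname constant_model
#' @export
oracle_model <- function(reference) {
  stopifnot(is.array(reference), length(dim(reference)) == 3L)
  structure(list(reference = reference), class = c("mvsir_oracle", "mvsir_stub"))
}

#' @rdname predict_voxels
#' @export
predict_voxels.mvsir_constant <- function(model, cube, centers, ...) {
  rep(model$p, nrow(centers))
}

#' @rdname predict_voxels
#' @export
predict_voxels.mvsir_oracle <- function(model, cube, centers, ...) {
  if (!identical(dim(model$reference), dim(cube$data)))
    stop_config("oracle_model: reference shape differs from cube shape")
  as.numeric(model$reference[cbind(centers$z, centers$y, centers$x)])
}

#' Predict a per-voxel confidence volume over a nodule cube
#'
#' Scores every cube voxel (or, with `stride > 1`, a regular subgrid with
#' nearest-neighbor fill — a cheaper desk-scale option) with the model's
#' nodule probability and reassembles the values by voxel position into a 3D
#' confidence volume aligned to the cube. The SH input comes from the cube's
#' consensus mask, matching the semi-automatic protocol in which reader ROIs
#' exist at test time.
#'
#' @param model A fitted [mvsir()] model or a stub from [constant_model()] /
#'   [oracle_model()].
#' @param cube A [nodule_cube()].
#' @param stride Positive integer subgrid stride (default 1 = every voxel).
#' @param ... Passed to the [predict_voxels()] method (e.g. `vh_normalize`,
#'   `chunk`).
#' @return An object of class `prediction_volume`: list with `confidence`
#'   (numeric array in `[0, 1]`, `NA` where not evaluated before fill),
#'   `evaluated` (logical array of directly scored voxels), `stride`.
#' @export
predict_cube <- function(model, cube, stride = 1L, ...) {
  stopifnot(inherits(cube, "nodule_cube"))
  if (!is_count(stride) || stride < 1) stop_config("predict_cube: stride must be >= 1")
  if (inherits(model, "mvsir") && cube_patch_mismatch(model, cube))
    stop_config("predict_cube: model patch size exceeds what the cube supports")
  dims <- dim(cube$data)
  zs <- seq(1L, dims[1], by = stride)
  ys <- seq(1L, dims[2], by = stride)
  xs <- seq(1L, dims[3], by = stride)
  centers <- data.frame(
    z = rep(zs, times = length(ys) * length(xs)),
    y = rep(rep(ys, each = length(zs)), times = length(xs)),
    x = rep(xs, each = length(zs) * length(ys)))
  probs <- predict_voxels(model, cube, centers, ...)
  conf <- array(NA_real_, dims)
  conf[cbind(centers$z, centers$y, centers$x)] <- probs
  evaluated <- array(FALSE, dims)
  evaluated[cbind(centers$z, centers$y, centers$x)] <- TRUE
  if (stride > 1L) {
    near <- function(idx, grid) grid[pmin(pmax(round((idx - 1) / stride) + 1, 1), length(grid))]
    full <- expand_grid_indices(dims)
    conf_full <- conf[cbind(near(full[, 1], zs), near(full[, 2], ys), near(full[, 3], xs))]
    conf <- array(conf_full, dims)
  }
  structure(list(confidence = conf, evaluated = evaluated, stride = as.integer(stride)),
            class = "prediction_volume")
}

cube_patch_mismatch <- function(model, cube) {
  # patches are clamped at cube borders, so any cube works; only guard against
  # a degenerate model/patch configuration
  model$net_config$patch_size < 2L
}

expand_grid_indices <- function(dims) {
  cbind(rep(seq_len(dims[1]), times = dims[2] * dims[3]),
        rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
        rep(seq_len(dims[3]), each = dims[1] * dims[2]))
}

#' @export
print.prediction_volume <- function(x, ...) {
  cat(sprintf("prediction_volume: %s voxels, %d evaluated (stride %d)\n",
              paste(dim(x$confidence), collapse = " x "), sum(x$evaluated),
              x$stride))
  invisible(x)
}

#' Threshold a confidence volume into a binary segmentation
#'
#' @param pred A [predict_cube()] result.
#' @param threshold Probability threshold in (0, 1); voxels with confidence
#'   `>= threshold` become mask voxels. The ROC-optimal threshold from
#'   [roc_optimal_threshold()] is a common choice.
#' @param provenance Optional list recorded with the result (model
#'   fingerprint, cube id, ...).
#' @return An object of class `segmentation_result`: list with `mask`
#'   (0/1 array), `threshold`, `n_voxels`, `provenance`.
#' @export
binarize <- function(pred, threshold, provenance = NULL) {
  stopifnot(inherits(pred, "prediction_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop_config("binarize: threshold must lie strictly inside (0, 1)")
  conf <- pred$confidence
  mask <- array(0L, dim(conf))
  ok <- !is.na(conf)
  mask[ok] <- as.integer(conf[ok] >= threshold)
  structure(list(mask = mask, threshold = threshold,
                 n_voxels = sum(mask), provenance = provenance),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d voxels at threshold %.3f\n",
              x$n_voxels, x$threshold))
  invisible(x)
}

#' Export a segmentation to NIfTI files in source-volume coordinates
#'
#' Writes the confidence volume and the binary mask as NIfTI (the mask
#' embedded at the cube's offset in a source-shaped volume) and an overlay
#' summary CSV of per-slice mask voxel counts.
#'
#' @param result A [binarize()] result.
#' @param pred The matching [predict_cube()] result.
#' @param cube The [nodule_cube()] that was predicted.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
reconstruct_export <- function(result, pred, cube, dir) {
  stopifnot(inherits(result, "segmentation_result"),
            inherits(pred, "prediction_volume"), inherits(cube, "nodule_cube"))
  if (!identical(dim(result$mask), dim(cube$data)))
    stop_config("reconstruct_export: mask and cube shapes differ")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conf <- pred$confidence
  conf[is.na(conf)] <- 0
  paths <- c(confidence = file.path(dir, "confidence.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"),
             mask_source = file.path(dir, "mask_source.nii.gz"),
             slice_counts = file.path(dir, "slice_counts.csv"))
  write_volume(volume_image(conf, cube$spacing), paths["confidence"])
  write_volume(volume_image(result$mask + 0, cube$spacing), paths["mask"])
  src <- array(0, cube$source_shape)
  d <- dim(result$mask)
  src[cube$offset[1] + seq_len(d[1]) - 1L,
      cube$offset[2] + seq_len(d[2]) - 1L,
      cube$offset[3] + seq_len(d[3]) - 1L] <- result$mask
  write_volume(volume_image(src, cube$spacing), paths["mask_source"])
  counts <- data.frame(slice = seq_len(d[1]),
                       source_slice = cube$offset[1] + seq_len(d[1]) - 1L,
                       mask_voxels = apply(result$mask, 1L, sum))
  write.csv(counts, paths["slice_counts"], row.names = FALSE)
  invisible(paths)
}
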