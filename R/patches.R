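# orthogonal-plane window indices around a center, clamped (edge replication)
# or marked out-of-bounds (constant fill)
patch_axes <- function(view) {
  switch(view,
         axial    = c(fix = 1L, row = 2L, col = 3L),  # plane (y, x)
         coronal  = c(fix = 2L, row = 1L, col = 3L),  # plane (z, x)
         sagittal = c(fix = 3L, row = 1L, col = 2L),  # plane (z, y)
         stop_config("invalid view '%s' (use axial, coronal or sagittal)", view))
}

extract_plane_patch <- function(arr, center, view, size, fill, fill_value = 0) {
  ax <- patch_axes(view)
  dims <- dim(arr)
  if (any(center < 1L) || any(center > dims))
    stop_config("patch center (%s) outside cube", paste(center, collapse = ","))
  half <- size %/% 2L
  rows <- center[ax["row"]] + ((-half):(half - 1L + size %% 2L))
  cols <- center[ax["col"]] + ((-half):(half - 1L + size %% 2L))
  rows_c <- pmin(pmax(rows, 1L), dims[ax["row"]])
  cols_c <- pmin(pmax(cols, 1L), dims[ax["col"]])
  idx <- matrix(0L, size * size, 3L)
  idx[, ax["fix"]] <- center[ax["fix"]]
  idx[, ax["row"]] <- rep(rows_c, times = size)
  idx[, ax["col"]] <- rep(cols_c, each = size)
  out <- matrix(arr[idx], size, size)
  if (fill == "constant") {
    oob_r <- rows < 1L | rows > dims[ax["row"]]
    oob_c <- cols < 1L | cols > dims[ax["col"]]
    out[oob_r, ] <- fill_value
    out[, oob_c] <- fill_value
  }
  out
}

#' Extract a voxel-heterogeneity (VH) patch
#'
#' The `size x size` grayscale window of the orthogonal plane through
#' `center` — axial fixes z (plane y, x), coronal fixes y (plane z, x),
#' sagittal fixes x (plane z, y) — with the center voxel at patch index
#' `(size %/% 2 + 1, size %/% 2 + 1)` (so a 30 x 30 patch spans
#' `center - 15 .. center + 14` per in-plane axis). Pixels falling outside
#' the cube are filled by edge replication by default.
#'
#' @param cube A [nodule_cube()].
#' @param center Integer voxel index `(z, y, x)` inside the cube.
#' @param view One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param size Patch side length (default 30).
#' @param fill `"replicate"` (default) or `"constant"` out-of-bounds fill.
#' @param fill_value Fill value when `fill = "constant"`.
#' @return A `size x size` numeric matrix.
#' @export
extract_vh_patch <- function(cube, center, view, size = 30L,
                             fill = c("replicate", "constant"), fill_value = 0) {
  stopifnot(inherits(cube, "nodule_cube"))
  fill <- match.arg(fill)
  extract_plane_patch(cube$data, as.integer(center), view, as.integer(size),
                      fill, fill_value)
}

#' Extract a shape-heterogeneity (SH) patch
#'
#' As [extract_vh_patch()] but sampling the consensus binary mask, so the
#' patch carries the nodule's shape/boundary information; output is strictly
#' 0/1.
#'
#' @inheritParams extract_vh_patch
#' @return A `size x size` 0/1 matrix.
#' @export
extract_sh_patch <- function(cube, center, view, size = 30L,
                             fill = c("replicate", "constant"), fill_value = 0) {
  stopifnot(inherits(cube, "nodule_cube"))
  fill <- match.arg(fill)
  out <- extract_plane_patch(cube$mask, as.integer(center), view,
                             as.integer(size), fill, fill_value)
  matrix(as.integer(out != 0), nrow(out), ncol(out))
}

# the fixed stream order binding patches to submodels
stream_names <- function() {
  c("axial_vh", "axial_sh", "coronal_vh", "coronal_sh",
    "sagittal_vh", "sagittal_sh")
}

#' Build the six aligned patch streams for a set of centers
#'
#' For every labeled center, extracts the six patches — 3 views x {VH, SH} —
#' in the fixed stream order `axial_vh, axial_sh, coronal_vh, coronal_sh,
#' sagittal_vh, sagittal_sh`. All six streams share the center ordering and
#' one label vector.
#'
#' @param cube A [nodule_cube()].
#' @param centers `data.frame` with columns `z, y, x, label` (from
#'   [sample_balanced_centers()], or any labeled center table).
#' @param size Patch side length (default 30).
#' @param fill,fill_value Out-of-bounds rule, see [extract_vh_patch()].
#' @param vh_normalize `"none"` (raw intensities) or `"minmax"` (per-cube
#'   linear rescale of VH patches to `[0, 1]`).
#' @return An object of class `patch_streams`: list with `streams` (named
#'   list of six `size x size x n` arrays), `labels`, `centers`, `size` and
#'   the fill/normalization settings.
#' @export
build_patch_streams <- function(cube, centers, size = 30L,
                                fill = c("replicate", "constant"),
                                fill_value = 0,
                                vh_normalize = c("none", "minmax")) {
  stopifnot(inherits(cube, "nodule_cube"))
  fill <- match.arg(fill)
  vh_normalize <- match.arg(vh_normalize)
  size <- as.integer(size)
  if (!all(c("z", "y", "x", "label") %in% names(centers)))
    stop_config("build_patch_streams: centers must have columns z, y, x, label")
  n <- nrow(centers)
  dat <- cube$data
  if (vh_normalize == "minmax") {
    rng <- range(dat)
    dat <- if (diff(rng) > 0) (dat - rng[1]) / diff(rng) else dat * 0
  }
  views <- c("axial", "coronal", "sagittal")
  streams <- stats::setNames(
    replicate(6L, array(0, c(size, size, max(n, 0L))), simplify = FALSE),
    stream_names())
  if (n > 0L) {
    cz <- as.integer(centers$z); cy <- as.integer(centers$y)
    cx <- as.integer(centers$x)
    for (i in seq_len(n)) {
      ctr <- c(cz[i], cy[i], cx[i])
      for (v in 1:3) {
        vh <- extract_plane_patch(dat, ctr, views[v], size, fill, fill_value)
        sh <- extract_plane_patch(cube$mask, ctr, views[v], size, fill, fill_value)
        streams[[2L * v - 1L]][, , i] <- vh
        streams[[2L * v]][, , i] <- as.integer(sh != 0)
      }
    }
  } else {
    streams <- stats::setNames(
      replicate(6L, array(0, c(size, size, 0L)), simplify = FALSE),
      stream_names())
  }
  structure(list(streams = streams,
                 labels = as.integer(centers$label),
                 centers = centers, size = size, fill = fill,
                 vh_normalize = vh_normalize),
            class = "patch_streams")
}

#' @export
print.patch_streams <- function(x, ...) {
  cat(sprintf("patch_streams: %d centers x 6 streams of %d x %d patches (%d positive)\n",
              length(x$labels), x$size, x$size, sum(x$labels)))
  invisible(x)
}

# flatten a stream to a (size*size) x n matrix for the network
stream_matrix <- function(streams, name) {
  a <- streams$streams[[name]]
  dim(a) <- c(streams$size * streams$size, dim(a)[3L])
  a
}

#' Persist / load patch streams
#'
#' Streams are written as an RDS archive next to a JSON manifest recording
#' the patch size, fill rule, normalization and stream ordering.
#'
#' @param streams A [build_patch_streams()] result.
#' @param dir Output directory.
#' @return `write_patch_streams` returns `dir` invisibly;
#'   `read_patch_streams` the `patch_streams` object.
#' @export
write_patch_streams <- function(streams, dir) {
  stopifnot(inherits(streams, "patch_streams"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(streams, file.path(dir, "streams.rds"), compress = "gzip")
  jsonlite::write_json(list(patch_size = streams$size, fill = streams$fill,
                            vh_normalize = streams$vh_normalize,
                            stream_order = stream_names(),
                            n = length(streams$labels)),
                       file.path(dir, "streams.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_patch_streams
#' @export
read_patch_streams <- function(dir) {
  readRDS(file.path(dir, "streams.rds"))
}
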