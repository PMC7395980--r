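#' Padded isotropic nodule cube
#'
#' A cropped sub-volume tightly containing a nodule plus a pad margin
#' (default 10 voxels on each of the six faces, which supplies the
#' non-nodule tissue that balances negative against positive samples),
#' together with the consensus binary mask on the same grid and the offset
#' locating the cube in its source volume.
#'
#' @param data Numeric 3D array `(z, y, x)`, isotropic voxels.
#' @param mask Integer 0/1 array, same shape as `data`.
#' @param pad Requested pad in voxels.
#' @param pad_effective `3 x 2` integer matrix of the pad actually applied on
#'   the (low, high) face of each axis after clipping at the volume border.
#' @param offset Integer length-3: 1-based index in the source volume of the
#'   cube's `(1, 1, 1)` voxel.
#' @param spacing Voxel spacing in mm.
#' @param source_shape Integer length-3 shape of the source volume.
#' @return An object of class `nodule_cube`.
#' @export
nodule_cube <- function(data, mask, pad, pad_effective, offset,
                        spacing = c(1, 1, 1), source_shape = dim(data)) {
  if (!identical(dim(data), dim(mask)))
    stop_config("nodule_cube: data and mask shapes differ")
  structure(list(data = data, mask = mask, pad = as.integer(pad),
                 pad_effective = pad_effective, offset = as.integer(offset),
                 spacing = as.numeric(spacing),
                 source_shape = as.integer(source_shape)),
            class = "nodule_cube")
}

#' @export
print.nodule_cube <- function(x, ...) {
  cat(sprintf("nodule_cube: %s voxels, pad %d, %d nodule voxels, offset (%s)\n",
              paste(dim(x$data), collapse = " x "), x$pad, sum(x$mask),
              paste(x$offset, collapse = ", ")))
  invisible(x)
}

#' Crop a padded nodule cube around a mask
#'
#' Crops the bounding box of the nonzero mask voxels, enlarged by `pad`
#' voxels on all six faces and clipped to the volume bounds; the per-face pad
#' actually applied is recorded. With no clipping, the cube extent per axis
#' is the mask bounding-box extent plus `2 * pad`.
#'
#' @param vol A [volume_image()].
#' @param mask Integer/logical array of the same shape as `vol$data`.
#' @param pad Pad in voxels on each face (default 10).
#' @return A [nodule_cube()].
#' @export
extract_cube <- function(vol, mask, pad = 10L) {
  stopifnot(inherits(vol, "volume_image"))
  if (!identical(dim(vol$data), dim(mask)))
    stop_config("extract_cube: volume and mask shapes differ")
  if (!is_count(pad) || pad < 0) stop_config("extract_cube: pad must be >= 0")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_config("extract_cube: empty mask")
  dims <- dim(mask)
  lo <- unname(pmax(apply(idx, 2L, min) - pad, 1L))
  hi <- unname(pmin(apply(idx, 2L, max) + pad, dims))
  idx_lo <- unname(apply(idx, 2L, min)); idx_hi <- unname(apply(idx, 2L, max))
  pad_eff <- cbind(low = idx_lo - lo, high = hi - idx_hi)
  nodule_cube(
    data = vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    mask = array(as.integer(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]),
                 hi - lo + 1L),
    pad = pad, pad_effective = pad_eff, offset = lo,
    spacing = vol$spacing, source_shape = dims)
}

#' Write / read a nodule cube as paired NIfTI plus JSON sidecar
#'
#' `data` and `mask` are written as NIfTI files and the pad, offset, source
#' shape and index convention as a JSON sidecar.
#'
#' @param cube A [nodule_cube()].
#' @param dir Output directory (created if needed).
#' @return `write_cube` returns `dir` invisibly; `read_cube` a
#'   [nodule_cube()].
#' @export
write_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "nodule_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(volume_image(cube$data, cube$spacing), file.path(dir, "data.nii.gz"))
  write_volume(volume_image(cube$mask + 0, cube$spacing), file.path(dir, "mask.nii.gz"))
  side <- list(pad = cube$pad,
               pad_effective = cube$pad_effective,
               offset = cube$offset,
               source_shape = cube$source_shape,
               spacing = cube$spacing,
               axis_order = "z,y,x",
               index_base = 1L)
  jsonlite::write_json(side, file.path(dir, "cube.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cube
#' @export
read_cube <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "cube.json"), simplifyVector = TRUE)
  dat <- read_volume(file.path(dir, "data.nii.gz"))
  msk <- read_volume(file.path(dir, "mask.nii.gz"))
  nodule_cube(dat$data, array(as.integer(round(msk$data)), dim(msk$data)),
              pad = side$pad, pad_effective = as.matrix(side$pad_effective),
              offset = side$offset, spacing = side$spacing,
              source_shape = side$source_shape)
}
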