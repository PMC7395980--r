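#' 3D scalar volume with voxel spacing
#'
#' The basic CT-like container: a 3D array in `(z, y, x)` axis order with
#' per-axis voxel spacing in mm. Voxel indices are 1-based and the center of
#' voxel `(i, j, k)` sits at physical coordinate `((i-1)*sz, (j-1)*sy,
#' (k-1)*sx)` mm relative to `origin`.
#'
#' @param data Numeric 3D array, axis order `(z, y, x)`.
#' @param spacing Numeric length-3 vector of voxel sizes in mm, `(z, y, x)`.
#' @param origin Numeric length-3 physical offset in mm (default zero).
#' @return An object of class `volume_image`.
#' @export
#' @examples
#' v <- volume_image(array(0, c(4, 5, 6)), spacing = c(2, 1, 1))
#' dim(v$data)
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_config("volume_image: 'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_config("volume_image: 'spacing' must be 3 positive numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %s voxels (z,y,x), spacing %s mm\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read / write a volume as NIfTI
#'
#' Volumes are stored with the NIfTI convention (fastest axis = x), so the
#' in-memory `(z, y, x)` array is transposed on the way out and back in; the
#' voxel spacing travels in the header `pixdim`.
#'
#' @param vol A [volume_image()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume_image()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  arr <- aperm(vol$data, c(3L, 2L, 1L))           # (x,y,z) for NIfTI
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, rev(vol$spacing)) # (x,y,z) mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop_config("read_volume: expected a 3D image")
  sp <- RNifti::pixdim(img)
  volume_image(aperm(arr, c(3L, 2L, 1L)), spacing = rev(sp[1:3]))
}

#' Resample a volume to isotropic voxel spacing
#'
#' Trilinear resampling onto a grid of `round(n * s_in / s_out)` voxels per
#' axis, which preserves the physical extent to within one voxel. Intensities
#' are interpolated trilinearly with edge clamping; a constant image is
#' reproduced exactly.
#'
#' @param vol A [volume_image()].
#' @param target_spacing Numeric length-3 target spacing in mm, default
#'   `c(1, 1, 1)` (the standard isotropic grid for nodule cubes).
#' @return A [volume_image()] with the requested spacing.
#' @export
#' @examples
#' v <- volume_image(array(rnorm(10 * 8 * 8), c(10, 8, 8)), spacing = c(2, 1, 1))
#' iso <- resample_isotropic(v)
#' dim(iso$data)   # 20 x 8 x 8
resample_isotropic <- function(vol, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(vol, "volume_image"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop_config("resample_isotropic: target spacing must be 3 positive numbers")
  n_in <- dim(vol$data)
  if (all(abs(vol$spacing - target_spacing) < 1e-12)) return(vol)
  n_out <- pmax(1L, as.integer(round(n_in * vol$spacing / target_spacing)))
  # separable trilinear interpolation, one axis at a time; the
  # lo + frac * (hi - lo) form reproduces constants exactly
  out <- vol$data
  for (a in 1:3) {
    if (n_out[a] == dim(out)[a] && abs(vol$spacing[a] - target_spacing[a]) < 1e-12)
      next
    src <- ((seq_len(n_out[a]) - 1) * target_spacing[a]) / vol$spacing[a] + 1
    src <- pmin(pmax(src, 1), n_in[a])
    lo <- pmin(floor(src), n_in[a] - (n_in[a] > 1L))
    fr <- src - lo
    hi <- pmin(lo + 1, n_in[a])
    take <- function(i) switch(a, out[i, , , drop = FALSE],
                               out[, i, , drop = FALSE],
                               out[, , i, drop = FALSE])
    A <- take(lo); B <- take(hi)
    w <- array(0, dim(A))
    if (a == 1L) w[] <- fr
    if (a == 2L) w[] <- rep(fr, each = dim(A)[1])
    if (a == 3L) w[] <- rep(fr, each = dim(A)[1] * dim(A)[2])
    out <- A + w * (B - A)
  }
  volume_image(out, spacing = target_spacing, origin = vol$origin)
}
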