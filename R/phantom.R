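#' Parameters of a synthetic nodule phantom
#'
#' Describes a CT-like cube containing one star-convex "bumpy ellipsoid"
#' nodule with analytic ground truth, plus simulated multi-reader contours.
#' Defaults emulate a small solid nodule read by four radiologists on a
#' 1 mm isotropic grid: ~3 mm semi-axes, mild lobulation, nodule density
#' around 40 HU on a -800 HU lung background, 10 HU acquisition noise and
#' 0.2 mm inter-reader contour jitter.
#'
#' @param grid_shape Integer length-3 `(z, y, x)` grid size in voxels.
#' @param spacing Voxel spacing in mm.
#' @param nodule_center Continuous voxel index `(z, y, x)` of the nodule
#'   center (1-based); default grid midpoint.
#' @param radii Ellipsoid semi-axes in mm `(z, y, x)`, all positive.
#' @param radial_bumpiness Amplitude in `[0, 1)` of a smooth low-order
#'   angular perturbation of the radius; 0 gives an exact ellipsoid and the
#'   shape stays star-convex about the center for any value below 1.
#' @param nodule_intensity,background_intensity HU-like scalar intensities.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian voxel noise.
#' @param n_readers Number of simulated readers (>= 1).
#' @param reader_jitter Per-vertex radial contour jitter in mm.
#' @param n_vertices Polygon vertices per slice contour (>= 16).
#' @param seed Integer seed fixing the bumpiness field, the noise and the
#'   reader jitter.
#' @return An object of class `phantom_params`.
#' @export
#' @examples
#' p <- phantom_params(grid_shape = c(36, 36, 36), radii = c(3, 3, 3))
phantom_params <- function(grid_shape = c(36, 36, 36),
                           spacing = c(1, 1, 1),
                           nodule_center = NULL,
                           radii = c(3, 3, 3),
                           radial_bumpiness = 0.1,
                           nodule_intensity = 40,
                           background_intensity = -800,
                           noise_sigma = 10,
                           n_readers = 4L,
                           reader_jitter = 0.2,
                           n_vertices = 96L,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_config("phantom_params: grid_shape must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_config("phantom_params: spacing must be 3 positive numbers")
  if (is.null(nodule_center)) nodule_center <- (grid_shape + 1) / 2
  if (length(nodule_center) != 3L)
    stop_config("phantom_params: nodule_center must have 3 components")
  if (length(radii) != 3L || any(radii <= 0))
    stop_config("phantom_params: radii must be 3 positive numbers (mm)")
  if (radial_bumpiness < 0 || radial_bumpiness >= 1)
    stop_config("phantom_params: radial_bumpiness must lie in [0, 1)")
  if (!is_count(n_readers) || n_readers < 1)
    stop_config("phantom_params: n_readers must be >= 1")
  if (!is_count(n_vertices) || n_vertices < 16)
    stop_config("phantom_params: n_vertices must be >= 16")
  if (noise_sigma < 0 || reader_jitter < 0)
    stop_config("phantom_params: noise_sigma and reader_jitter must be >= 0")
  # the nodule plus the standard 10-voxel pad must fit inside the grid
  max_extent_vox <- radii * (1 + radial_bumpiness) / spacing
  lo <- nodule_center - max_extent_vox - 10
  hi <- nodule_center + max_extent_vox + 10
  if (any(lo < 1) || any(hi > grid_shape))
    stop_config(paste("phantom_params: grid too small to contain the nodule",
                      "plus a 10-voxel pad"))
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 nodule_center = as.numeric(nodule_center),
                 radii = as.numeric(radii),
                 radial_bumpiness = radial_bumpiness,
                 nodule_intensity = nodule_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 n_readers = as.integer(n_readers),
                 reader_jitter = reader_jitter,
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Smooth angular radius-perturbation field drawn deterministically from the
# seed: f(theta, phi) = 1 + bump * g, with g a low-order trigonometric series
# normalized to [-1, 1]. theta is the polar angle from +z, phi the azimuth.
bump_field <- function(params) {
  k_max <- 3L
  cf <- with_seed(derive_seed(params$seed, "bump"), {
    list(a = runif(k_max, -1, 1),
         p = runif(k_max, 0, 2 * pi),
         q = runif(k_max, 0, 2 * pi))
  })
  norm <- sum(abs(cf$a))
  if (norm == 0) norm <- 1
  function(theta, phi) {
    g <- 0
    for (k in seq_len(k_max)) {
      g <- g + cf$a[k] * sin(k * theta + cf$p[k]) * cos(k * phi + cf$q[k])
    }
    1 + params$radial_bumpiness * g / norm
  }
}

# ellipsoid-normalized radius and angles of physical offsets d (n x 3, mm)
shape_rho <- function(d, params, f) {
  rho <- sqrt((d[, 1] / params$radii[1])^2 + (d[, 2] / params$radii[2])^2 +
              (d[, 3] / params$radii[3])^2)
  len <- sqrt(rowSums(d^2))
  theta <- ifelse(len > 0, acos(pmin(pmax(d[, 1] / pmax(len, 1e-300), -1), 1)), 0)
  phi <- atan2(d[, 2], d[, 3])
  rho / f(theta, phi)
}

#' Analytic ground-truth nodule mask
#'
#' Marks voxel `v` as nodule iff its physical center lies inside the (possibly
#' bumpy) ellipsoid: `rho(v) <= f(theta, phi)` where `rho` is the
#' ellipsoid-normalized radius and `f` the seed-determined angular
#' perturbation field. Deterministic given the seed.
#'
#' @param params A [phantom_params()].
#' @return Integer 0/1 array of dimension `grid_shape`.
#' @export
analytic_mask <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  f <- bump_field(params)
  gs <- params$grid_shape
  zi <- (seq_len(gs[1]) - params$nodule_center[1]) * params$spacing[1]
  yi <- (seq_len(gs[2]) - params$nodule_center[2]) * params$spacing[2]
  xi <- (seq_len(gs[3]) - params$nodule_center[3]) * params$spacing[3]
  d <- cbind(rep(zi, times = gs[2] * gs[3]),
             rep(rep(yi, each = gs[1]), times = gs[3]),
             rep(xi, each = gs[1] * gs[2]))
  array(as.integer(shape_rho(d, params, f) <= 1), gs)
}

# boundary radius t (mm) of the nodule on axial slice z along in-plane angle
# alpha, or NA if the on-axis point of that slice is outside the shape
contour_radius <- function(z, alpha, params, f) {
  dz <- (z - params$nodule_center[1]) * params$spacing[1]
  g <- function(t) {
    d <- matrix(c(dz, t * sin(alpha), t * cos(alpha)), ncol = 3L)
    shape_rho(d, params, f) - 1
  }
  t_eps <- 1e-9
  if (g(t_eps) >= 0) return(NA_real_)  # on-axis point of this slice is outside
  tmax <- max(params$radii) * (1 + params$radial_bumpiness) * 1.01
  if (g(tmax) <= 0) return(tmax)
  stats::uniroot(g, c(t_eps, tmax), tol = 1e-10)$root
}

#' Generate a synthetic nodule phantom
#'
#' Builds the CT-like volume (`background + contrast * mask + noise`), the
#' analytic ground-truth mask, and per-reader slice contours: for every axial
#' slice intersecting the nodule, the analytic boundary polygon is sampled at
#' `n_vertices` angles and each reader's copy receives i.i.d. radial vertex
#' jitter of scale `reader_jitter` mm (clipped away from the centroid so the
#' polygon stays simple). Everything is fixed by the seed.
#'
#' @param params A [phantom_params()].
#' @return An object of class `phantom_case`: list with elements `volume`
#'   (a [volume_image()]), `gt_mask` (0/1 array), `annotations` (list of
#'   [slice_annotation()]), and `params`.
#' @export
#' @examples
#' case <- generate_phantom(phantom_params(seed = 7))
#' sum(case$gt_mask)
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  f <- bump_field(params)
  gt <- analytic_mask(params)
  gs <- params$grid_shape
  contrast <- params$nodule_intensity - params$background_intensity
  noise <- if (params$noise_sigma > 0) {
    with_seed(derive_seed(params$seed, "noise"),
              array(rnorm(prod(gs), sd = params$noise_sigma), gs))
  } else array(0, gs)
  vol <- volume_image(params$background_intensity + contrast * gt + noise,
                      spacing = params$spacing)
  alphas <- seq(0, 2 * pi, length.out = params$n_vertices + 1L)[-(params$n_vertices + 1L)]
  annotations <- with_seed(derive_seed(params$seed, "readers"), {
    anns <- list()
    for (z in seq_len(gs[1])) {
      t0 <- vapply(alphas, function(a) contour_radius(z, a, params, f), numeric(1))
      if (anyNA(t0) || all(t0 <= 0)) next
      for (r in seq_len(params$n_readers)) {
        t_r <- t0
        if (params$reader_jitter > 0) {
          t_r <- t0 + rnorm(length(t0), sd = params$reader_jitter)
          t_r <- pmax(t_r, 0.05 * t0)
        }
        verts <- cbind(
          params$nodule_center[2] + t_r * sin(alphas) / params$spacing[2],
          params$nodule_center[3] + t_r * cos(alphas) / params$spacing[3])
        anns[[length(anns) + 1L]] <- slice_annotation(r, z, verts)
      }
    }
    anns
  })
  structure(list(volume = vol, gt_mask = gt, annotations = annotations,
                 params = params),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case: grid %s, %d nodule voxels, %d contours (%d readers)\n",
              paste(x$params$grid_shape, collapse = " x "), sum(x$gt_mask),
              length(x$annotations), x$params$n_readers))
  invisible(x)
}

#' Write / read phantom annotations as JSON
#'
#' Schema: a top-level object documenting the axis order and index base, and
#' an `annotations` array of `{reader_id, slice_index, vertices: [[y,x],...]}`
#' records in continuous 1-based voxel coordinates.
#'
#' @param annotations List of [slice_annotation()] objects.
#' @param path JSON file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations` a
#'   list of [slice_annotation()].
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, function(a) {
    list(reader_id = a$reader, slice_index = a$slice,
         vertices = unname(apply(a$vertices, 1L, function(v) c(v[1], v[2]),
                                 simplify = FALSE)))
  })
  jsonlite::write_json(list(axis_order = "z,y,x", index_base = 1L,
                            annotations = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj$annotations, function(rec) {
    v <- do.call(rbind, lapply(rec$vertices, function(p) c(p[[1]], p[[2]])))
    slice_annotation(rec$reader_id, rec$slice_index, v)
  })
}

#' Write a phantom case to a directory
#'
#' Emits `volume.nii.gz`, `gt_mask.nii.gz`, `annotations.json` and a
#' `manifest.json` listing the files, the generator parameters and the seed.
#'
#' @param case A `phantom_case` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$volume, file.path(dir, "volume.nii.gz"))
  write_volume(volume_image(case$gt_mask + 0, case$params$spacing),
               file.path(dir, "gt_mask.nii.gz"))
  write_annotations(case$annotations, file.path(dir, "annotations.json"))
  manifest <- list(files = c("volume.nii.gz", "gt_mask.nii.gz", "annotations.json"),
                   params = unclass(case$params),
                   seed = case$params$seed,
                   axis_order = "z,y,x", index_base = 1L)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
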