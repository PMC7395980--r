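#' Per-slice polygonal reader annotation
#'
#' One reader's nodule contour on one axial slice: an ordered list of polygon
#' vertices in continuous in-plane voxel coordinates `(y, x)` of the grid the
#' annotation refers to (voxel centers at integer coordinates, 1-based).
#'
#' @param reader Integer reader id (>= 1).
#' @param slice Integer axial slice index (1-based z).
#' @param vertices Numeric `n x 2` matrix of `(y, x)` vertices, `n >= 3`,
#'   describing a simple (non self-intersecting) polygon.
#' @return An object of class `slice_annotation`.
#' @export
slice_annotation <- function(reader, slice, vertices) {
  vertices <- as.matrix(vertices)
  if (!is_count(reader) || reader < 1) stop_config("reader must be a positive integer")
  if (!is_count(slice) || slice < 1) stop_config("slice must be a positive integer")
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop_config("vertices must be an n x 2 matrix with n >= 3")
  structure(list(reader = as.integer(reader), slice = as.integer(slice),
                 vertices = unname(vertices)),
            class = "slice_annotation")
}

#' Ray-casting point-in-polygon test
#'
#' Casts a ray in the `+x` direction from each query point and counts
#' crossings with the polygon edges; an odd count means inside. Edges use a
#' half-open vertex rule (`[y_low, y_high)`) so a ray passing exactly through
#' a vertex is counted once, and points lying exactly on the boundary are
#' reported as inside.
#'
#' @param points Numeric `n x 2` matrix (or length-2 vector) of `(y, x)`
#'   query points.
#' @param poly Numeric `m x 2` matrix of ordered `(y, x)` polygon vertices,
#'   `m >= 3`.
#' @return Logical vector of length `n`: `TRUE` for inside (or on the
#'   boundary).
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' point_in_polygon(c(5, 5), sq)    # TRUE
#' point_in_polygon(c(5, 15), sq)   # FALSE
point_in_polygon <- function(points, poly) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points <- as.matrix(points)
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop_config("point_in_polygon: polygon needs >= 3 vertices")
  py <- points[, 1L]; px <- points[, 2L]
  n <- nrow(points); m <- nrow(poly)
  crossings <- integer(n)
  on_edge <- logical(n)
  scale <- max(abs(poly), 1)
  eps <- 1e-9 * scale
  j <- m
  for (i in seq_len(m)) {
    y1 <- poly[j, 1L]; x1 <- poly[j, 2L]
    y2 <- poly[i, 1L]; x2 <- poly[i, 2L]
    # boundary: |cross product| small and point within the segment's span
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on_edge <- on_edge | (abs(cr) <= eps * sqrt(max(len2, eps)) &
                          dot >= -eps & dot <= len2 + eps)
    spans <- (y1 <= py & py < y2) | (y2 <= py & py < y1)
    if (any(spans)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(spans & px < xint)
    }
    j <- i
  }
  (crossings %% 2L == 1L) | on_edge
}

# TRUE if the polygon has no self-intersections (adjacent edges excluded).
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  m <- nrow(poly)
  if (m < 3L) return(FALSE)
  seg <- cbind(poly, poly[c(2:m, 1L), ])
  inter <- function(a, b) {
    d1 <- sign((b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1]))
    d2 <- sign((b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1]))
    d3 <- sign((a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1]))
    d4 <- sign((a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1]))
    d1 != d2 && d3 != d4
  }
  for (i in seq_len(m - 2L)) {
    jmax <- if (i == 1L) m - 1L else m
    for (j in (i + 2L):jmax) {
      # a and b are (y1,x1,y2,x2) rows; swap to (x,y) consistent form not needed
      if (inter(seg[i, c(2, 1, 4, 3)], seg[j, c(2, 1, 4, 3)])) return(FALSE)
    }
  }
  TRUE
}

# reader ids present in an annotation list
annotation_readers <- function(annotations) {
  sort(unique(vapply(annotations, function(a) a$reader, integer(1))))
}

#' Label a voxel center as nodule / non-nodule
#'
#' Majority vote across readers of the ray-casting inside test against each
#' reader's polygon(s) on the center's axial slice: a reader votes 1 if the
#' point is inside any of its polygons on that slice, readers with no contour
#' on the slice vote 0, and the label is 1 when the mean vote is `>= 0.5`
#' (ties toward inclusion). A slice with no contours at all labels 0. By
#' construction this coincides with [consensus_mask()] at voxel centers.
#'
#' @param center Numeric length-3 voxel index `(z, y, x)`, 1-based.
#' @param annotations List of [slice_annotation()] objects (any slices; only
#'   those on `center[1]` are consulted).
#' @param readers Optional integer vector of reader ids forming the vote
#'   denominator; defaults to all readers present in `annotations`.
#' @return Integer 0 or 1.
#' @export
label_center <- function(center, annotations, readers = NULL) {
  stopifnot(length(center) == 3L)
  if (length(annotations) == 0L) return(0L)
  if (is.null(readers)) readers <- annotation_readers(annotations)
  if (length(readers) == 0L) return(0L)
  z <- as.integer(round(center[1L]))
  p <- c(center[2L], center[3L])
  votes <- vapply(readers, function(r) {
    polys <- Filter(function(a) a$reader == r && a$slice == z, annotations)
    any(vapply(polys, function(a) point_in_polygon(p, a$vertices), logical(1)))
  }, logical(1))
  as.integer(mean(votes) >= 0.5)
}

#' Fuse multi-reader contours into a consensus binary mask
#'
#' Each reader's polygons are rasterized by evaluating the ray-casting inside
#' test at every voxel center of the affected slices; the per-voxel mean of
#' the reader masks is thresholded at `>= 0.5` (majority, ties toward
#' inclusion). With unanimous readers the consensus equals any single
#' reader's rasterization.
#'
#' @param annotations Non-empty list of [slice_annotation()] objects.
#' @param shape Integer length-3 grid shape `(z, y, x)`.
#' @param readers Optional reader ids forming the vote denominator.
#' @return Integer 0/1 array of dimension `shape`.
#' @export
consensus_mask <- function(annotations, shape, readers = NULL) {
  if (length(annotations) == 0L) stop_config("consensus_mask: empty annotation set")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L)
  if (is.null(readers)) readers <- annotation_readers(annotations)
  for (a in annotations) {
    if (!inherits(a, "slice_annotation"))
      stop_config("consensus_mask: annotations must be slice_annotation objects")
    if (!polygon_is_simple(a$vertices))
      stop_config("consensus_mask: self-intersecting polygon (reader %d, slice %d)",
                  a$reader, a$slice)
  }
  votes <- array(0, shape)
  slices <- sort(unique(vapply(annotations, function(a) a$slice, integer(1))))
  for (z in slices) {
    if (z < 1L || z > shape[1L]) next
    plane_votes <- matrix(0, shape[2L], shape[3L])
    for (r in readers) {
      polys <- Filter(function(a) a$reader == r && a$slice == z, annotations)
      if (length(polys) == 0L) next
      inside <- matrix(FALSE, shape[2L], shape[3L])
      for (a in polys) {
        v <- a$vertices
        ylo <- max(1L, floor(min(v[, 1L]))); yhi <- min(shape[2L], ceiling(max(v[, 1L])))
        xlo <- max(1L, floor(min(v[, 2L]))); xhi <- min(shape[3L], ceiling(max(v[, 2L])))
        if (ylo > yhi || xlo > xhi) next
        pts <- cbind(rep(ylo:yhi, times = xhi - xlo + 1L),
                     rep(xlo:xhi, each = yhi - ylo + 1L))
        hit <- point_in_polygon(pts, v)
        inside[cbind(pts[hit, 1L], pts[hit, 2L])] <- TRUE
      }
      plane_votes <- plane_votes + inside
    }
    votes[z, , ] <- plane_votes
  }
  array(as.integer(votes / length(readers) >= 0.5), shape)
}

#' Balanced center-sampling plan
#'
#' @param per_slice_n Number of centers drawn per annotated slice (>= 2). The
#'   full-scale protocol uses 4000; the desk-scale default is 200.
#' @param balance Fraction of positive (in-nodule) centers per slice, in
#'   (0, 1); default 0.5 for class balance.
#' @param seed Integer RNG seed for the draw.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(per_slice_n = 200, balance = 0.5, seed = 1) {
  if (!is_count(per_slice_n) || per_slice_n < 2)
    stop_config("sampling_plan: per_slice_n must be an integer >= 2")
  if (!is.numeric(balance) || balance <= 0 || balance >= 1)
    stop_config("sampling_plan: balance must be in (0, 1)")
  structure(list(per_slice_n = as.integer(per_slice_n), balance = balance,
                 seed = as.integer(seed)),
            class = "sampling_plan")
}

#' Draw balanced nodule / background training centers
#'
#' For every axial slice of the cube that intersects the nodule (consensus
#' mask nonzero), draws exactly `per_slice_n` voxel centers:
#' `round(balance * per_slice_n)` from inside the consensus mask and the rest
#' from outside it on the same slice. Sampling is without replacement when
#' the voxel pool suffices, otherwise with replacement (recorded in the
#' `replaced` column). Deterministic given the plan seed.
#'
#' @param cube A [nodule_cube()].
#' @param plan A [sampling_plan()].
#' @param slices Optional integer vector of slice indices to sample from;
#'   defaults to all slices with at least one positive voxel. Requested
#'   slices without positives are skipped with a warning.
#' @return A `data.frame` with columns `z, y, x, label, slice, replaced`.
#' @export
sample_balanced_centers <- function(cube, plan, slices = NULL) {
  stopifnot(inherits(cube, "nodule_cube"), inherits(plan, "sampling_plan"))
  mask <- cube$mask
  pos_per_slice <- apply(mask, 1L, sum)
  if (is.null(slices)) slices <- which(pos_per_slice > 0)
  if (length(slices) == 0L)
    stop_config("sample_balanced_centers: no slice intersects the nodule")
  n_pos <- as.integer(round(plan$balance * plan$per_slice_n))
  n_neg <- plan$per_slice_n - n_pos
  dims <- dim(mask)
  out <- with_seed(plan$seed, {
    rows <- vector("list", length(slices))
    for (k in seq_along(slices)) {
      z <- slices[k]
      plane <- mask[z, , ]
      pos_idx <- which(plane == 1L)
      neg_idx <- which(plane == 0L)
      if (length(pos_idx) == 0L) {
        warning(sprintf("slice %d has no positive voxels; skipped", z))
        next
      }
      if (length(neg_idx) == 0L) {
        warning(sprintf("slice %d has no negative voxels; skipped", z))
        next
      }
      draw <- function(idx, n) {
        repl <- length(idx) < n
        list(i = sample(idx, n, replace = repl), repl = repl)
      }
      dp <- draw(pos_idx, n_pos); dn <- draw(neg_idx, n_neg)
      flat <- c(dp$i, dn$i)
      rows[[k]] <- data.frame(
        z = z,
        y = ((flat - 1L) %% dims[2L]) + 1L,
        x = ((flat - 1L) %/% dims[2L]) + 1L,
        label = rep(c(1L, 0L), c(n_pos, n_neg)),
        slice = z,
        replaced = rep(c(dp$repl, dn$repl), c(n_pos, n_neg)))
    }
    do.call(rbind, rows)
  })
  if (is.null(out))
    stop_config("sample_balanced_centers: no usable slices")
  rownames(out) <- NULL
  out
}

#' Persist / load center samples as CSV
#'
#' @param centers Center `data.frame` from [sample_balanced_centers()].
#' @param path CSV path.
#' @return `write_centers` returns `path` invisibly; `read_centers` the
#'   `data.frame`.
#' @export
write_centers <- function(centers, path) {
  write.csv(centers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centers
#' @export
read_centers <- function(path) {
  read.csv(path)
}
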