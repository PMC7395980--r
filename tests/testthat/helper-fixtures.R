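# Shared fixtures: tiny phantoms and polygons built in code at test time.

tiny_phantom_params <- function(seed = 1, ...) {
  defaults <- list(grid_shape = c(30L, 30L, 30L), radii = c(2, 2, 2),
                   radial_bumpiness = 0, noise_sigma = 0, reader_jitter = 0,
                   n_readers = 2L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_params, args)
}

# a cube around an ellipsoidal nodule with consensus mask, ready for patches
tiny_cube <- function(seed = 1, pad = 10L, ...) {
  case <- generate_phantom(tiny_phantom_params(seed = seed, ...))
  cons <- consensus_mask(case$annotations, dim(case$volume$data))
  list(case = case,
       cube = extract_cube(case$volume, cons, pad = pad))
}

# unit square polygon (y, x) vertex order
square_poly <- function(lo = 0, hi = 10) {
  rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi))
}

# concave "C" shape: a square with a rectangular bite out of the right side
c_poly <- function() {
  rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0), c(8, 0), c(8, 8),
        c(2, 8), c(2, 0))
}

# independent winding-number inside test (angle summation oracle)
winding_inside <- function(p, poly) {
  v <- sweep(poly, 2L, p)
  n <- nrow(v)
  total <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    ang <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    total <- total + ang
  }
  abs(total) > pi
}

# random simple star-shaped polygon about a center
random_star_polygon <- function(n_vertices = 12, r_range = c(2, 8),
                                center = c(0, 0)) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_range[1], r_range[2])
  cbind(center[1] + r * sin(ang), center[2] + r * cos(ang))
}

# random small binary mask pair for metric oracles
random_mask <- function(dims = c(8, 8, 8), p = 0.3) {
  array(as.integer(runif(prod(dims)) < p), dims)
}

tiny_net_config <- function(...) {
  net_config(stem_channels = 4L, rb1_widths = c(4L, 4L, 4L),
             c4_channels = 8L, rb2_widths = c(8L, 8L, 8L),
             fc_width = 16L, fusion_width = 16L, ...)
}
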