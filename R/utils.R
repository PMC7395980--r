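#' @useDynLib mvsir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif predict coef
#' @importFrom utils write.csv read.csv modifyList
NULL

# Run code with a temporarily fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific random seed from a global seed
#'
#' One global seed fans out to per-stage seeds so that stages are individually
#' reproducible without sharing an RNG stream. The derivation hashes the stage
#' name into the global seed (splitmix-style integer mixing, kept below 2^31).
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"phantom"` or `"train"`.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "phantom")
#' derive_seed(1, "train")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 2166136261
  for (b in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  out <- (as.numeric(seed) * 48271 + h) %% (2^31 - 1)
  as.integer(out) + 1L
}

# Short stable hash of a config (hex string); used to tag run artifacts.
# FNV-1a style mixing folded to 2^31 to stay in R-integer range.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# index (1-based) -> physical mm coordinate of the voxel center
index_to_mm <- function(idx, spacing) {
  sweep(idx - 1, 2L, spacing, `*`)
}
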