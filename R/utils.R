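#' Derive a child seed from a master seed
#'
#' All generators in the package take an explicit integer seed so that a
#' single master seed can be fanned out to independent, reproducible
#' sub-streams (one per participant, one per module stage). The split is a
#' fixed affine map modulo the Lehmer modulus 2^31 - 1, so child seeds stay
#' inside R's integer range and distinct streams never collide for
#' `stream < 48271`.
#'
#' @param seed master seed (integer).
#' @param stream non-negative integer identifying the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  as.integer((abs(as.double(seed)) %% m * 48271 + as.double(stream) + 1) %% m)
}

# Moving RMS over a window of `w` samples; the window is centred and
# truncated at the edges (partial windows use the samples present).
moving_rms <- function(x, w) as.vector(moving_rms_cpp(x, as.integer(w)))

# Length of the intersection of two closed intervals given as c(lo, hi).
interval_intersection_length <- function(a, b) {
  max(0, min(a[2], b[2]) - max(a[1], b[1]))
}

# For each row of `points` (p x 3), the distance to the nearest row of
# `vertices` (v x 3). Vectorised all-pairs computation; fine at the mesh
# sizes this package works with.
nearest_vertex_distance <- function(points, vertices) {
  points <- rbind(points)
  d2 <- outer(rowSums(points^2), rowSums(vertices^2), "+") -
    2 * points %*% t(vertices)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
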