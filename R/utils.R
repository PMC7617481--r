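# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-component child seed from a single master seed, kept within
# the 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647)
}

# Fold an angular difference (radians) into [0, period/2] for axial
# quantities (period pi for orientation, 2*pi for direction).
fold_angle_diff <- function(delta, period) {
  d <- abs(delta) %% period
  pmin(d, period - d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Flatten a T x H x W array into a T x (H*W) matrix (column-major within
# each frame, the package-wide pixel ordering).
flatten_frames <- function(frames) {
  d <- dim(frames)
  matrix(frames, nrow = d[1L], ncol = d[2L] * d[3L])
}

# Extract time slice t of an (n x B x T) array as an n x B matrix without
# dimension dropping.
slice_t <- function(A, t) {
  d <- dim(A)
  matrix(A[, , t], nrow = d[1L], ncol = d[2L])
}
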