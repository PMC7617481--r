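#' Construct a movie clip
#'
#' A `movie_clip` is the package's elementary stimulus: a grayscale
#' spatiotemporal array of `T` frames of `H x W` pixels, nominally zero-mean.
#' Clips are consumed by the recurrent network as flattened frame vectors
#' (column-major within each frame).
#'
#' @param frames Numeric array of dimension `T x H x W` with `T >= 2` and all
#'   values finite.
#' @param frame_rate Nominal frame rate in Hz (metadata only).
#' @param role Either `"input"` or `"target"`; records which side of the
#'   prediction pairing the clip plays.
#' @return An object of class `movie_clip`.
#' @export
movie_clip <- function(frames, frame_rate = 25, role = c("input", "target")) {
  role <- match.arg(role)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (time x height x width)")
  }
  if (dim(frames)[1L] < 2L) stop("a movie clip needs at least 2 frames")
  if (!all(is.finite(frames))) stop("`frames` contains non-finite values")
  structure(
    list(frames = frames, frame_rate = frame_rate, role = role),
    class = "movie_clip"
  )
}

#' @export
print.movie_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<movie_clip> %d frames of %dx%d px (%s, %g Hz), sd %.3f\n",
    d[1L], d[2L], d[3L], x$role, x$frame_rate, stats::sd(x$frames)
  ))
  invisible(x)
}

#' Number of frames in a clip
#' @param clip A `movie_clip`.
#' @return Integer frame count.
#' @export
n_frames <- function(clip) dim(clip$frames)[1L]

#' Frame size of a clip
#' @param clip A `movie_clip`.
#' @return Integer vector `c(H, W)`.
#' @export
frame_size <- function(clip) dim(clip$frames)[2:3]

#' Flatten a clip to a time-by-pixels matrix
#'
#' @param clip A `movie_clip`.
#' @return A `T x (H*W)` numeric matrix, pixels in column-major frame order.
#' @export
clip_matrix <- function(clip) flatten_frames(clip$frames)

#' Construct a labelled stimulus set
#'
#' Bundles a list of clips with a per-clip metadata table (one row per clip):
#' stimulus class, orientation/direction, spatial and temporal frequency,
#' deviant position, and whatever else a generator records.
#'
#' @param clips List of `movie_clip` objects.
#' @param labels A `data.frame` with one row per clip.
#' @return An object of class `stimulus_set`.
#' @export
stimulus_set <- function(clips, labels) {
  stopifnot(is.list(clips), is.data.frame(labels))
  if (length(clips) != nrow(labels)) {
    stop("`labels` must have exactly one row per clip")
  }
  structure(list(clips = clips, labels = labels), class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "<stimulus_set> %d clips; classes: %s\n",
    length(x$clips),
    paste(unique(as.character(x$labels$stimulus_class)), collapse = ", ")
  ))
  invisible(x)
}
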