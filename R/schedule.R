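#' PET frame schedule
#'
#' An ordered set of frame time intervals defining the temporal sampling of a
#' dynamic PET acquisition. Frames must be non-overlapping, in increasing
#' order, with all times in seconds.
#'
#' @param starts Numeric vector of frame start times (s).
#' @param ends Numeric vector of frame end times (s), same length as `starts`.
#' @return An object of class `frame_schedule` with elements `starts` and
#'   `ends`.
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 2, 4))
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends))
    stop("'starts' and 'ends' must have the same length")
  if (length(starts) < 2L)
    stop("a frame schedule needs at least 2 frames")
  if (anyNA(starts) || anyNA(ends) || any(!is.finite(starts)) ||
      any(!is.finite(ends)))
    stop("frame times must be finite")
  if (any(starts < 0))
    stop("frame times must be non-negative")
  if (any(ends <= starts))
    stop("each frame end must exceed its start")
  if (any(diff(starts) < 0) || any(starts[-1L] < ends[-length(ends)] - 1e-9))
    stop("frames must be ordered and non-overlapping")
  structure(list(starts = starts, ends = ends), class = "frame_schedule")
}

#' High-temporal-resolution early-dynamic frame schedule
#'
#' The HTR protocol for the first 2 minutes of a dynamic scan: 60 frames of
#' 1 s followed by 30 frames of 2 s, covering 0-120 s.
#'
#' @return A [frame_schedule()] with 90 frames.
#' @examples
#' sched <- htr_schedule()
#' n_frames(sched)       # 90
#' range(sched$ends)     # up to 120 s
#' @export
htr_schedule <- function() {
  starts <- c(0:59, seq(60, 118, by = 2))
  ends <- c(1:60, seq(62, 120, by = 2))
  frame_schedule(starts, ends)
}

#' @rdname frame_schedule
#' @param x A `frame_schedule`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  length(x$starts)
}

#' Frame durations and midpoints
#'
#' @param x A [frame_schedule()].
#' @return Numeric vector of per-frame durations (s) or midpoints (s).
#' @export
frame_durations <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  x$ends - x$starts
}

#' @rdname frame_durations
#' @export
frame_mids <- function(x) {
  stopifnot(inherits(x, "frame_schedule"))
  (x$starts + x$ends) / 2
}

#' @export
print.frame_schedule <- function(x, ...) {
  n <- n_frames(x)
  cat(sprintf("<frame_schedule> %d frames, %.6g-%.6g s\n",
              n, x$starts[1L], x$ends[n]))
  invisible(x)
}

schedules_equal <- function(a, b, tol = 1e-9) {
  n_frames(a) == n_frames(b) &&
    max(abs(a$starts - b$starts)) <= tol &&
    max(abs(a$ends - b$ends)) <= tol
}
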