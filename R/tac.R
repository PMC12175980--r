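#' Time-activity curve
#'
#' Frame-averaged activity-concentration measurements (kBq/mL) for one region
#' or voxel, tied to a [frame_schedule()].
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric vector of activity concentrations (kBq/mL), one per
#'   frame.
#' @param label Optional free-text region label.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, label = "") {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule))
    stop("'values' length must equal the number of frames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values,
                 label = as.character(label)[1L]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s%d frames, peak %.4g kBq/mL\n",
              if (nzchar(x$label)) paste0("'", x$label, "', ") else "",
              n_frames(x$schedule), max(x$values)))
  invisible(x)
}

#' Arterial input function sampled on a uniform fine grid
#'
#' Holds the arterial (blood-pool) tracer concentration Ca(t) driving tissue
#' kinetics. The grid must be uniform with spacing of at most 0.5 s so that
#' sub-second vascular transit is resolved.
#'
#' @param times Numeric vector of sample times (s), uniformly spaced from 0.
#' @param values Non-negative activity concentrations (kBq/mL).
#' @return An object of class `arterial_input` with elements `times`,
#'   `values` and `dt`.
#' @export
arterial_input <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (length(times) < 3L)
    stop("the arterial input needs at least 3 samples")
  dt <- diff(times)
  if (any(abs(dt - dt[1L]) > 1e-6 * max(dt[1L], 1)))
    stop("the arterial input grid must be uniform")
  dt <- dt[1L]
  if (dt <= 0 || dt > 0.5 + 1e-9)
    stop("the arterial input spacing must be positive and at most 0.5 s")
  if (anyNA(values) || any(!is.finite(values)) || any(values < -1e-12))
    stop("arterial input values must be finite and non-negative")
  structure(list(times = times, values = pmax(values, 0), dt = dt),
            class = "arterial_input")
}

#' @export
print.arterial_input <- function(x, ...) {
  cat(sprintf("<arterial_input> %d samples, dt = %.3g s, peak %.4g kBq/mL\n",
              length(x$times), x$dt, max(x$values)))
  invisible(x)
}

#' Read and write TAC tables
#'
#' Delimited text with columns `frame_start_s`, `frame_end_s`,
#' `value_kBq_per_mL` and, for long-format multi-region files, `region`.
#'
#' @param path File path.
#' @return `read_tac_table()` returns a single [tac()] or a named list of
#'   them when a `region` column is present.
#' @export
read_tac_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("frame_start_s", "frame_end_s", "value_kBq_per_mL")
  if (!all(need %in% names(d)))
    stop("TAC table must contain columns: ", paste(need, collapse = ", "))
  if ("region" %in% names(d)) {
    out <- lapply(split(d, d$region), function(g) {
      tac(frame_schedule(g$frame_start_s, g$frame_end_s),
          g$value_kBq_per_mL, label = g$region[1L])
    })
    out
  } else {
    tac(frame_schedule(d$frame_start_s, d$frame_end_s), d$value_kBq_per_mL)
  }
}

#' @rdname read_tac_table
#' @param x A [tac()] or named list of them.
#' @export
write_tac_table <- function(x, path) {
  rows <- if (inherits(x, "tac")) list(x) else x
  d <- do.call(rbind, lapply(rows, function(tt) {
    data.frame(region = tt$label,
               frame_start_s = tt$schedule$starts,
               frame_end_s = tt$schedule$ends,
               value_kBq_per_mL = tt$values)
  }))
  if (inherits(x, "tac") && !nzchar(x$label)) d$region <- NULL
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tac_table
#' @export
read_aif_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("time_s", "value_kBq_per_mL")
  if (!all(need %in% names(d)))
    stop("AIF table must contain columns: ", paste(need, collapse = ", "))
  arterial_input(d$time_s, d$value_kBq_per_mL)
}

#' @rdname read_tac_table
#' @param aif An [arterial_input()].
#' @export
write_aif_table <- function(aif, path) {
  stopifnot(inherits(aif, "arterial_input"))
  utils::write.table(
    data.frame(time_s = aif$times, value_kBq_per_mL = aif$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
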