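#' Grid configuration for basis-function fitting
#'
#' Defines the discrete search grids over the nonlinear parameters of the
#' basis-function estimator: clearance rate `k2` (geometric spacing), mean
#' vascular transit time `Tc` and arterial time delay `td` (linear spacing),
#' plus the residual weighting scheme and the non-negativity flag for the
#' linear coefficients.
#'
#' Defaults span the regional values reported for early FDG kinetics with
#' generous margin: `k2` in \[0.01, 3\]/min over 50 geometric nodes, `Tc` in
#' \[0, 40\] s and `td` in \[0, 30\] s, both in 0.5 s steps.
#'
#' @param k2 Ascending positive grid of clearance rates (1/min).
#' @param Tc Ascending non-negative grid of transit times (s); ignored for
#'   S1TC fitting.
#' @param td Ascending non-negative grid of time delays (s).
#' @param weighting Residual weighting scheme; see [fit_weights()].
#' @param nonneg Enforce non-negative linear coefficients.
#' @return An object of class `grid_config`.
#' @examples
#' grid_config()
#' grid_config(Tc = seq(0, 32, 1), td = seq(0, 10, 1))  # coarser, voxel-scale
#' @export
grid_config <- function(k2 = exp(seq(log(0.01), log(3), length.out = 50)),
                        Tc = seq(0, 40, by = 0.5),
                        td = seq(0, 30, by = 0.5),
                        weighting = c("frame_duration", "uniform",
                                      "inverse_variance"),
                        nonneg = TRUE) {
  weighting <- match.arg(weighting)
  chk_grid <- function(g, nm, positive = FALSE) {
    if (length(g) < 1L || anyNA(g) || any(!is.finite(g)))
      stop("'", nm, "' grid must be non-empty and finite")
    if (is.unsorted(g, strictly = TRUE))
      stop("'", nm, "' grid must be strictly ascending")
    if (positive && any(g <= 0)) stop("'", nm, "' grid must be positive")
    if (!positive && any(g < 0)) stop("'", nm, "' grid must be non-negative")
    as.numeric(g)
  }
  structure(list(k2 = chk_grid(k2, "k2", positive = TRUE),
                 Tc = chk_grid(Tc, "Tc"),
                 td = chk_grid(td, "td"),
                 weighting = weighting,
                 nonneg = isTRUE(nonneg)),
            class = "grid_config")
}

#' @export
print.grid_config <- function(x, ...) {
  cat(sprintf(
    "<grid_config> k2: %d nodes [%.3g, %.3g]/min; Tc: %d nodes [%g, %g] s; td: %d nodes [%g, %g] s; weighting: %s\n",
    length(x$k2), min(x$k2), max(x$k2),
    length(x$Tc), min(x$Tc), max(x$Tc),
    length(x$td), min(x$td), max(x$td), x$weighting))
  invisible(x)
}

#' Read a grid configuration from a YAML or JSON file
#'
#' The file mirrors [grid_config()] field-for-field; absent fields take the
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [grid_config()].
#' @export
read_grid_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("k2", "Tc", "td", "weighting", "nonneg")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown grid config fields: ",
                        paste(bad, collapse = ", "))
  do.call(grid_config, cfg)
}

#' Residual weights for least-squares fitting
#'
#' \describe{
#'   \item{`uniform`}{all ones.}
#'   \item{`frame_duration`}{the frame duration (s), equalizing information
#'     content between 1 s and 2 s frames; the default.}
#'   \item{`inverse_variance`}{`duration / max(value, floor)`, the usual
#'     count-noise approximation, with a positive floor at 5% of the TAC
#'     peak to keep near-zero frames from dominating.}
#' }
#'
#' @param x A [tac()].
#' @param scheme Weighting scheme tag.
#' @return Positive numeric weight vector, one per frame.
#' @export
fit_weights <- function(x, scheme = c("frame_duration", "uniform",
                                      "inverse_variance")) {
  stopifnot(inherits(x, "tac"))
  scheme <- match.arg(scheme)
  dur <- frame_durations(x$schedule)
  switch(scheme,
    uniform = rep(1, length(dur)),
    frame_duration = dur,
    inverse_variance = {
      floor_val <- max(0.05 * max(x$values), 1e-6)
      dur / pmax(x$values, floor_val)
    })
}
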