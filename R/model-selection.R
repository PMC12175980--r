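#' Akaike information criterion for a least-squares fit
#'
#' Gaussian-likelihood form `AIC = n * ln(RSS / n) + 2k`, with an optional
#' small-sample correction (AICc) adding `2k(k+1)/(n-k-1)`. The
#' free-parameter counts are 5 for AATH (F, K1, k2, Tc, td) and 4 for S1TC
#' (vb, K1, k2, td). Lower is better.
#'
#' @param rss Weighted residual sum of squares, `> 0` (a tiny positive floor
#'   guards exact zeros).
#' @param n Number of frames; must exceed `k`.
#' @param k Number of free parameters.
#' @param correct Apply the small-sample (AICc) correction.
#' @return The AIC value.
#' @examples
#' aic(1, 90, 4)   # 90 * log(1/90) + 8
#' @export
aic <- function(rss, n, k, correct = FALSE) {
  if (!is.numeric(rss) || length(rss) != 1L || is.na(rss) || rss < 0)
    stop("'rss' must be a single non-negative number")
  if (n <= k) stop("'n' must exceed 'k'")
  rss <- max(rss, 1e-300)
  out <- n * log(rss / n) + 2 * k
  if (correct) {
    if (n <= k + 1) stop("AICc requires n > k + 1")
    out <- out + 2 * k * (k + 1) / (n - k - 1)
  }
  out
}

#' @rdname aic
#' @param fit A [fit_tac()] result.
#' @export
aic_fit <- function(fit, correct = FALSE) {
  stopifnot(inherits(fit, "fit_result"))
  aic(fit$rss, fit$n, fit$k, correct = correct)
}

#' Frame-average a TAC to a coarser temporal resolution
#'
#' Partitions the scan duration into contiguous bins of the given interval
#' and sets each output value to the duration-weighted mean of the input
#' frames overlapping the bin. Averaging can merge but never split measured
#' frames: bin boundaries that would fall strictly inside a frame longer
#' than the interval are dropped (so a 1 s interval leaves native 2 s frames
#' intact), while shorter frames straddling a boundary contribute by
#' duration-weighted overlap. The duration-weighted time-integral of the TAC
#' is conserved exactly.
#'
#' @param x A [tac()] whose frames tile the scan without gaps.
#' @param interval Target frame interval (s); the scan duration must be a
#'   whole number of intervals.
#' @return A [tac()] on the coarser schedule.
#' @examples
#' frame_average(tac(htr_schedule(), rexp(90)), 10)  # 12 frames of 10 s
#' @export
frame_average <- function(x, interval) {
  stopifnot(inherits(x, "tac"))
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0)
    stop("'interval' must be a single positive number of seconds")
  s <- x$schedule
  t0 <- s$starts[1L]
  t1 <- s$ends[n_frames(s)]
  span <- t1 - t0
  if (abs(span / interval - round(span / interval)) > 1e-9)
    stop("scan duration (", span, " s) is not a whole number of ",
         interval, " s intervals")
  if (any(abs(s$starts[-1L] - s$ends[-n_frames(s)]) > 1e-9))
    stop("frame averaging requires a gap-free schedule")
  edges <- seq(t0, t1, by = interval)
  # drop edges strictly interior to frames longer than the interval
  keep <- vapply(edges, function(e) {
    inside <- which(s$starts < e - 1e-9 & s$ends > e + 1e-9)
    length(inside) == 0L || (s$ends[inside] - s$starts[inside]) <= interval + 1e-9
  }, logical(1L))
  edges <- edges[keep]
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    a <- edges[b]; e <- edges[b + 1L]
    ov <- pmin(s$ends, e) - pmax(s$starts, a)
    ov[ov < 0] <- 0
    out[b] <- sum(ov * x$values) / sum(ov)
  }
  tac(frame_schedule(edges[-length(edges)], edges[-1L]), out, label = x$label)
}

#' Compare AATH and S1TC fits of one TAC
#'
#' Fits both models with prebuilt bases and reports their AICs and the
#' difference (AATH minus S1TC); negative values favor the distributed
#' model.
#'
#' @param x A [tac()].
#' @param basis_aath,basis_s1tc [build_basis()] tables for the two models on
#'   the TAC's schedule.
#' @param correct Use AICc.
#' @return A one-row data frame with columns `region`, `interval_s`,
#'   `aic_aath`, `aic_s1tc`, `delta_aic`.
#' @export
model_comparison <- function(x, basis_aath, basis_s1tc, correct = FALSE) {
  fa <- fit_tac(x, basis_aath)
  fs <- fit_tac(x, basis_s1tc)
  aa <- aic_fit(fa, correct)
  as <- aic_fit(fs, correct)
  data.frame(region = x$label,
             interval_s = mean(frame_durations(x$schedule)),
             aic_aath = aa, aic_s1tc = as, delta_aic = aa - as)
}

#' Temporal-resolution model-selection study
#'
#' Frame-averages a measured HTR TAC at each requested interval, rebuilds
#' the basis tables on the coarser schedule, fits both models, and records
#' AIC differences -- reproducing the resolution dependence of
#' AATH-vs-S1TC preference.
#'
#' @param x A [tac()] on the HTR schedule.
#' @param aif The [arterial_input()] driving the fits.
#' @param intervals Frame intervals (s), a subset of `c(1, 2, 3, 5, 10)`.
#' @param grid A [grid_config()].
#' @param correct Use AICc.
#' @return A data frame, one row per interval, with columns as in
#'   [model_comparison()] (with `interval_s` the nominal interval).
#' @export
temporal_resolution_study <- function(x, aif, intervals = c(1, 2, 3, 5, 10),
                                      grid = grid_config(),
                                      correct = FALSE) {
  stopifnot(inherits(x, "tac"))
  if (!all(intervals %in% c(1, 2, 3, 5, 10)))
    stop("'intervals' must be a subset of {1, 2, 3, 5, 10}")
  rows <- lapply(intervals, function(iv) {
    xa <- frame_average(x, iv)
    ba <- build_basis(aif, xa$schedule, grid, "aath")
    bs <- build_basis(aif, xa$schedule, grid, "s1tc")
    row <- model_comparison(xa, ba, bs, correct)
    row$interval_s <- iv
    row
  })
  do.call(rbind, rows)
}

#' Bland-Altman and correlation agreement statistics
#'
#' Paired-method agreement between two measurement vectors: mean difference
#' `a - b`, 95% limits of agreement (mean difference +/- 1.96 SD of the
#' differences), Pearson correlation, and ordinary least-squares slope and
#' intercept of `a` on `b`. Zero-variance inputs raise an error rather than
#' returning a conventional value.
#'
#' @param a,b Numeric vectors of paired measurements, length >= 3, finite.
#' @return A list with `mean_diff`, `sd_diff`, `loa` (length-2 lower/upper),
#'   `correlation`, `slope`, `intercept`, `n`.
#' @examples
#' with(bland_altman(c(1, 2, 3.1), c(1.1, 2.1, 3)), c(mean_diff, loa))
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have the same length")
  if (length(a) < 3L) stop("at least 3 pairs are required")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be finite")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("zero-variance input: correlation and regression are undefined")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  fit <- stats::lm.fit(cbind(1, b), a)
  list(mean_diff = md,
       sd_diff = sdd,
       loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
       correlation = stats::cor(a, b),
       slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       n = length(a))
}
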