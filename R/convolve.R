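# Fine-grid numerical machinery shared by the forward model and the
# basis-function estimator. Everything operates on a uniform grid of spacing
# `dt` (default 0.1 s, >= 10x finer than the shortest HTR frame). All shifts
# are implemented as convex combinations of two integer-sample lags, so that
# shifting commutes exactly with the (linear, time-invariant) convolution and
# running-integral operators -- the forward model and the basis tables then
# agree to machine precision.

FINE_DT <- 0.1

fine_times <- function(t_end, dt = FINE_DT) {
  seq(0, t_end, by = dt)
}

# Linear interpolation of the AIF onto the fine grid; zero before the first
# sample, error if the AIF ends before `t_end`.
resample_aif <- function(aif, t_end, dt = FINE_DT) {
  stopifnot(inherits(aif, "arterial_input"))
  if (max(aif$times) < t_end - 1e-9)
    stop("arterial input does not cover the requested time range (",
         format(t_end), " s)")
  tf <- fine_times(t_end, dt)
  stats::approx(aif$times, aif$values, xout = tf, yleft = 0,
                yright = aif$values[length(aif$values)])$y
}

# Right-shift a fine-grid signal by `shift_s` seconds with zero fill,
# fractional shifts as a weighted pair of integer lags.
shift_fine <- function(x, shift_s, dt = FINE_DT) {
  if (shift_s < 0) stop("only non-negative shifts are supported")
  k <- floor(shift_s / dt + 1e-9)
  f <- shift_s / dt - k
  if (f < 1e-9) f <- 0
  n <- length(x)
  lag_k <- function(k) {
    if (k >= n) return(numeric(n))
    c(numeric(k), x[seq_len(n - k)])
  }
  if (f == 0) lag_k(k) else (1 - f) * lag_k(k) + f * lag_k(k + 1L)
}

# Causal exponential convolution y(t) = int_0^t x(s) exp(-k2 (t-s)/60) ds
# (time in seconds, k2 per minute), trapezoidal recursion.
conv_exp_fine <- function(x, k2, dt = FINE_DT) {
  e <- exp(-k2 * dt / 60)
  xlag <- c(0, x[-length(x)])
  as.numeric(stats::filter(dt * (x + e * xlag) / 2, e, method = "recursive"))
}

# Cumulative trapezoidal integral from 0.
cumtrapz_fine <- function(x, dt = FINE_DT) {
  dt * (cumsum(x) - (x + x[1L]) / 2)
}

# Weight vector w such that sum(w * q) equals the integral of the
# piecewise-linear interpolant of q over [0, x].
integ_weights_upto <- function(x, n, dt = FINE_DT) {
  w <- numeric(n)
  if (x <= 0) return(w)
  j <- min(floor(x / dt + 1e-9), n - 1L)  # complete segments 1..j
  if (j >= 1L) {
    w[seq_len(j + 1L)] <- dt
    w[1L] <- dt / 2
    w[j + 1L] <- dt / 2
  }
  u <- x - j * dt
  if (u > 1e-12 && j + 1L <= n - 1L) {
    w[j + 1L] <- w[j + 1L] + u - u^2 / (2 * dt)
    w[j + 2L] <- w[j + 2L] + u^2 / (2 * dt)
  }
  w
}

# Dense matrix A (n_frames x n_fine) with A %*% q = per-frame time-averages
# of the piecewise-linear interpolant of the fine-grid signal q.
frame_avg_matrix <- function(schedule, n_fine, dt = FINE_DT) {
  nf <- n_frames(schedule)
  A <- matrix(0, nf, n_fine)
  for (i in seq_len(nf)) {
    a <- schedule$starts[i]
    b <- schedule$ends[i]
    A[i, ] <- (integ_weights_upto(b, n_fine, dt) -
               integ_weights_upto(a, n_fine, dt)) / (b - a)
  }
  A
}
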