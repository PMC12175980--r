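#' Forward TAC model
#'
#' Computes the noise-free tissue time-activity curve for a delayed arterial
#' input convolved with the model impulse response,
#' `Q(t) = Ca(t - td) (x) R(t)`, then averages Q over each frame interval.
#'
#' The two models decompose into an intravascular and an extravascular
#' component:
#' \describe{
#'   \item{S1TC}{`Q(t) = vb * Ca(t - td) + K1 * [Ca(t - td) (x) exp(-k2 t / 60)]`
#'     -- the intravascular term is a scaled copy of the input.}
#'   \item{AATH}{`Q(t) = (F/60) * int_0^Tc Ca(t - td - s) ds +
#'     K1 * [Ca(t - td - Tc) (x) exp(-k2 t / 60)]` -- the intravascular term
#'     is the input smoothed over the vascular transit time Tc.}
#' }
#' Convolutions are evaluated on a uniform fine grid (0.1 s) with `Ca(t) = 0`
#' for `t < 0`; rate units (per minute) against second time axes carry the
#' 1/60 conversion.
#'
#' @param params An [aath_params()] or [s1tc_params()] object.
#' @param aif An [arterial_input()] covering the frame schedule.
#' @param schedule A [frame_schedule()].
#' @param dt Fine-grid spacing (s).
#' @param label Label for the returned TAC.
#' @return A [tac()].
#' @examples
#' aif <- generate_aif(aif_params())
#' forward_tac(aath_params(0.5, 0.14, 0.45, Tc = 4.4, td = 2),
#'             aif, htr_schedule())
#' @export
forward_tac <- function(params, aif, schedule, dt = FINE_DT, label = "") {
  stopifnot(inherits(schedule, "frame_schedule"))
  t_end <- schedule$ends[n_frames(schedule)]
  ca <- resample_aif(aif, t_end, dt)
  q <- forward_fine(params, ca, dt)
  A <- frame_avg_matrix(schedule, length(ca), dt)
  tac(schedule, as.numeric(A %*% q), label = label)
}

# Continuous-time (fine-grid) tissue curve for either model.
forward_fine <- function(params, ca, dt = FINE_DT) {
  if (inherits(params, "s1tc_params")) {
    cs <- shift_fine(ca, params$td, dt)
    ck <- shift_fine(conv_exp_fine(ca, params$k2, dt) / 60, params$td, dt)
    params$vb * cs + params$K1 * ck
  } else if (inherits(params, "aath_params")) {
    i1 <- cumtrapz_fine(ca, dt) / 60
    b1 <- shift_fine(i1, params$td, dt) -
      shift_fine(i1, params$td + params$Tc, dt)
    b2 <- shift_fine(conv_exp_fine(ca, params$k2, dt) / 60,
                     params$td + params$Tc, dt)
    params$flow * b1 + params$K1 * b2
  } else {
    stop("'params' must be an aath_params or s1tc_params object")
  }
}
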