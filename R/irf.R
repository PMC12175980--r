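#' Tissue impulse response functions
#'
#' The impulse response R(t) of each kinetic model: the tissue concentration
#' response to an instantaneous unit arterial bolus. Time is in seconds;
#' rates are per minute, so exponential arguments carry a 1/60 conversion.
#'
#' For the S1TC model, R(0) = vb (the instantaneous-mixing vascular term; as
#' a point value it is dimensionally a volume fraction and enters the forward
#' model as an additive `vb * Ca` term rather than through the convolution)
#' and R(t) = K1 exp(-k2 t / 60) for t > 0.
#'
#' For the AATH model, R(t) = F during the plug-flow vascular phase
#' (0 <= t < Tc) and R(t) = K1 exp(-k2 (t - Tc) / 60) in the tissue phase
#' (t >= Tc). The discontinuity at t = Tc is right-continuous with value K1.
#'
#' @param t Time(s) in seconds, `>= 0`. Vectorized.
#' @param p An [s1tc_params()] or [aath_params()] object.
#' @return Response values (mL/min/cm^3 in the tissue phase).
#' @examples
#' aath_irf(c(0, 2, 5, 65), aath_params(0.6, 0.2, 0.693, Tc = 5))
#' @export
s1tc_irf <- function(t, p) {
  stopifnot(inherits(p, "s1tc_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("'t' must be >= 0")
  ifelse(t == 0, p$vb, p$K1 * exp(-p$k2 * t / 60))
}

#' @rdname s1tc_irf
#' @export
aath_irf <- function(t, p) {
  stopifnot(inherits(p, "aath_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("'t' must be >= 0")
  ifelse(t < p$Tc, p$flow, p$K1 * exp(-p$k2 * (t - p$Tc) / 60))
}
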