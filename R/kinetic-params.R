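#' Kinetic parameter vectors
#'
#' Parameter containers for the two tissue models. Rates follow the usual
#' perfusion-literature units -- `F` and `K1` in mL/min/cm^3, `k2` in 1/min --
#' while all time quantities (`Tc`, `td`, frame times) are in seconds; unit
#' conversions by 60 are applied internally wherever a rate multiplies a
#' time.
#'
#' `s1tc_params()` describes the standard one-tissue compartment model:
#' fractional blood volume `vb`, blood-to-tissue transport rate `K1`,
#' clearance rate `k2` and arterial time delay `td`.
#'
#' `aath_params()` describes the adiabatic approximation to tissue
#' homogeneity (AATH) distributed model: blood flow `F` (named `flow` to
#' avoid clashing with `base::F`), `K1`, `k2`, mean vascular transit time
#' `Tc` and delay `td`. The extraction fraction `E = K1/F` must lie in
#' `[0, 1]`, and the implied blood volume `vb = F * Tc / 60` must lie in
#' `[0, 1]`.
#'
#' @param vb Fractional blood volume (mL/cm^3), in `[0, 1]`.
#' @param K1 Blood-to-tissue transport rate (mL/min/cm^3), `>= 0`.
#' @param k2 Clearance rate (1/min), `>= 0`.
#' @param td Time delay (s).
#' @param flow Blood flow F (mL/min/cm^3), `> 0`.
#' @param Tc Mean vascular transit time (s), `>= 0`.
#' @return An object of class `s1tc_params` or `aath_params`.
#' @examples
#' aath_params(flow = 0.507, K1 = 0.136, k2 = 0.45, Tc = 4.4, td = 2)
#' @export
s1tc_params <- function(vb, K1, k2, td = 0) {
  chk_num(vb, "vb"); chk_num(K1, "K1"); chk_num(k2, "k2"); chk_num(td, "td")
  if (vb < 0 || vb > 1) stop("'vb' must be in [0, 1]")
  if (K1 < 0) stop("'K1' must be >= 0")
  if (k2 < 0) stop("'k2' must be >= 0")
  structure(list(vb = vb, K1 = K1, k2 = k2, td = td), class = "s1tc_params")
}

#' @rdname s1tc_params
#' @export
aath_params <- function(flow, K1, k2, Tc, td = 0) {
  chk_num(flow, "flow"); chk_num(K1, "K1"); chk_num(k2, "k2")
  chk_num(Tc, "Tc"); chk_num(td, "td")
  if (flow <= 0) stop("'flow' must be > 0")
  if (K1 < 0) stop("'K1' must be >= 0")
  if (K1 > flow * (1 + 1e-9))
    stop("'K1' must not exceed 'flow' (extraction fraction <= 1)")
  if (k2 < 0) stop("'k2' must be >= 0")
  if (Tc < 0) stop("'Tc' must be >= 0")
  vb <- flow * Tc / 60
  if (vb > 1 + 1e-9)
    stop("implied blood volume flow*Tc/60 exceeds 1")
  structure(list(flow = flow, K1 = min(K1, flow), k2 = k2, Tc = Tc, td = td),
            class = "aath_params")
}

chk_num <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", nm))
}

#' Extraction fraction
#'
#' First-pass extraction fraction `E = K1 / F`: the fraction of delivered
#' tracer transported across the capillary wall, so that `K1 = F * E`.
#'
#' @param flow Blood flow F (mL/min/cm^3), `> 0`.
#' @param K1 Transport rate (mL/min/cm^3), with `0 <= K1 <= flow`.
#' @return E, unitless in `[0, 1]`.
#' @examples
#' extraction_fraction(0.507, 0.136)
#' @export
extraction_fraction <- function(flow, K1) {
  chk_num(flow, "flow"); chk_num(K1, "K1")
  if (flow <= 0) stop("'flow' must be > 0")
  if (K1 < 0 || K1 > flow * (1 + 1e-9))
    stop("'K1' must lie in [0, flow]")
  min(K1 / flow, 1)
}

#' Mean vascular transit time
#'
#' `Tc = vb / F`, converted to seconds (`F` is per minute): the time for
#' tracer to traverse the whole vascular volume of a voxel at plug flow.
#'
#' @param vb Fractional blood volume (mL/cm^3), `>= 0`.
#' @param flow Blood flow F (mL/min/cm^3), `> 0`.
#' @return Tc in seconds.
#' @examples
#' vascular_transit_time(0.05, 1)  # 3 s
#' @export
vascular_transit_time <- function(vb, flow) {
  chk_num(vb, "vb"); chk_num(flow, "flow")
  if (flow <= 0) stop("'flow' must be > 0")
  if (vb < 0) stop("'vb' must be >= 0")
  60 * vb / flow
}

#' @export
print.aath_params <- function(x, ...) {
  cat(sprintf(
    "<aath_params> F=%.4g K1=%.4g k2=%.4g /min Tc=%.4g s td=%.4g s (E=%.3g, vb=%.3g)\n",
    x$flow, x$K1, x$k2, x$Tc, x$td, extraction_fraction(x$flow, x$K1),
    x$flow * x$Tc / 60))
  invisible(x)
}

#' @export
print.s1tc_params <- function(x, ...) {
  cat(sprintf("<s1tc_params> vb=%.4g K1=%.4g k2=%.4g /min td=%.4g s\n",
              x$vb, x$K1, x$k2, x$td))
  invisible(x)
}
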