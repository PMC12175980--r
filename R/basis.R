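# Basis-function tables for grid-search least squares.
#
# Both models are linear in two coefficients once the nonlinear parameters
# are fixed, so fitting reduces to a 2-regressor weighted least-squares
# solve at every grid node:
#   AATH (k2, Tc, td):  Q = F * B1 + K1 * B2,
#     B1(t) = (1/60) int_0^Tc Ca(t - td - s) ds
#     B2(t) = (1/60) [Ca(t - td - Tc) (x) exp(-k2 t / 60)]
#   S1TC (k2, td):      Q = vb * X1 + K1 * X2,
#     X1(t) = Ca(t - td),  X2(t) = (1/60) [Ca(t - td) (x) exp(-k2 t / 60)]
# The regressors factor through shared precomputations: one running integral
# of the AIF, one exponential convolution per k2 node, and frame averaging.
# Shifting by td (and Tc) is a lag of those fine-grid curves, so the basis
# stores only frame-averaged shifted copies indexed per node, plus the
# weight-dependent Gram entries needed for the closed-form 2x2 solve.

#' Precompute basis-function tables
#'
#' Builds the frame-averaged regressor tables and per-node Gram entries for
#' basis-function fitting of one model against one arterial input and frame
#' schedule. The basis is built once per AIF/schedule and reused across any
#' number of TACs (regional fits, replicates, voxels).
#'
#' @param aif An [arterial_input()] covering the schedule.
#' @param schedule A [frame_schedule()].
#' @param grid A [grid_config()].
#' @param model `"aath"` or `"s1tc"`.
#' @param dt Fine-grid spacing (s).
#' @return An object of class `kinetic_basis` for use with [fit_tac()].
#' @examples
#' aif <- generate_aif(aif_params())
#' basis <- build_basis(aif, htr_schedule(), grid_config(), "aath")
#' @export
build_basis <- function(aif, schedule, grid, model = c("aath", "s1tc"),
                        dt = FINE_DT) {
  model <- match.arg(model)
  stopifnot(inherits(aif, "arterial_input"),
            inherits(schedule, "frame_schedule"),
            inherits(grid, "grid_config"))
  t_end <- schedule$ends[n_frames(schedule)]
  ca <- resample_aif(aif, t_end, dt)
  nfine <- length(ca)
  A <- frame_avg_matrix(schedule, nfine, dt)
  nf <- n_frames(schedule)
  k2 <- grid$k2; Tc <- grid$Tc; td <- grid$td
  nk <- length(k2); nT <- length(Tc); nd <- length(td)

  shift_cols <- function(x, shifts) {
    vapply(shifts, function(s) shift_fine(x, s, dt), numeric(nfine))
  }

  if (model == "aath") {
    dmat <- round(outer(td, Tc, "+"), 9)            # nd x nT delay+transit
    dset <- sort(unique(as.vector(dmat)))
    nD <- length(dset)
    sset <- sort(unique(c(round(td, 9), dset)))      # all shifts of I1
    iS_td <- match(round(td, 9), sset)
    iS_dl <- matrix(match(dmat, sset), nd, nT)
    iD <- matrix(match(dmat, dset), nd, nT)

    i1 <- cumtrapz_fine(ca, dt) / 60
    J <- A %*% shift_cols(i1, sset)                  # nf x nS
    M <- matrix(0, nf, nk * nD)
    for (i in seq_len(nk)) {
      ck <- conv_exp_fine(ca, k2[i], dt) / 60
      M[, (i - 1L) * nD + seq_len(nD)] <- A %*% shift_cols(ck, dset)
    }
    # node enumeration: td slowest, then Tc, k2 fastest (tie-break order)
    l <- rep(seq_len(nd), each = nT * nk)
    j <- rep(rep(seq_len(nT), each = nk), times = nd)
    i <- rep(seq_len(nk), times = nd * nT)
    n1 <- iS_td[l]
    n2 <- iS_dl[cbind(l, j)]
    c2 <- (i - 1L) * nD + iD[cbind(l, j)]
    node_Tc <- Tc[j]
    b <- structure(list(model = model, schedule = schedule, grid = grid,
                        dt = dt, J = J, M = M,
                        n1 = n1, n2 = n2, c2 = c2, node_Tc = node_Tc,
                        nk = nk, nT = nT, nd = nd),
                   class = "kinetic_basis")
  } else {
    sset <- round(td, 9)
    X1 <- A %*% shift_cols(ca, td)                   # nf x nd
    M <- matrix(0, nf, nk * nd)
    for (i in seq_len(nk)) {
      ck <- conv_exp_fine(ca, k2[i], dt) / 60
      M[, (i - 1L) * nd + seq_len(nd)] <- A %*% shift_cols(ck, td)
    }
    l <- rep(seq_len(nd), each = nk)
    i <- rep(seq_len(nk), times = nd)
    n1 <- l
    c2 <- (i - 1L) * nd + l
    b <- structure(list(model = model, schedule = schedule, grid = grid,
                        dt = dt, J = X1, M = M,
                        n1 = n1, n2 = NULL, c2 = c2, node_Tc = NULL,
                        nk = nk, nT = 1L, nd = nd),
                   class = "kinetic_basis")
  }
  # Gram entries for the schedule-determined default weights; data-dependent
  # (inverse-variance) weights trigger a per-fit recompute in fit_tac().
  if (grid$weighting != "inverse_variance") {
    b$w0 <- fit_weights(tac(schedule, rep(1, nf)), grid$weighting)
    b$gram0 <- basis_gram(b, b$w0)
  }
  b
}

#' @export
print.kinetic_basis <- function(x, ...) {
  cat(sprintf("<kinetic_basis> model %s, %d frames, %d grid nodes\n",
              toupper(x$model), n_frames(x$schedule), length(x$n1)))
  invisible(x)
}

# Per-node Gram entries <x1,x1>_w, <x1,x2>_w, <x2,x2>_w.
basis_gram <- function(basis, w) {
  J <- basis$J; M <- basis$M
  wM <- w * M
  g22 <- colSums(M * wM)
  Qm <- crossprod(J, wM)
  if (basis$model == "aath") {
    P <- crossprod(J, w * J)
    Pd <- diag(P)
    G11 <- Pd[basis$n1] - 2 * P[cbind(basis$n1, basis$n2)] + Pd[basis$n2]
    G12 <- Qm[cbind(basis$n1, basis$c2)] - Qm[cbind(basis$n2, basis$c2)]
  } else {
    G11 <- colSums(J * (w * J))[basis$n1]
    G12 <- Qm[cbind(basis$n1, basis$c2)]
  }
  list(G11 = pmax(G11, 0), G12 = G12, G22 = pmax(g22[basis$c2], 0))
}

# Frame-averaged regressor pair at one node.
basis_regressors <- function(basis, node) {
  if (basis$model == "aath") {
    x1 <- basis$J[, basis$n1[node]] - basis$J[, basis$n2[node]]
  } else {
    x1 <- basis$J[, basis$n1[node]]
  }
  list(x1 = x1, x2 = basis$M[, basis$c2[node]])
}
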