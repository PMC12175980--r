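#' Fit a time-activity curve by basis-function least squares
#'
#' Exhaustively searches the (k2, Tc, td) grid of a precomputed
#' [build_basis()] table, solving the 2-coefficient weighted linear
#' least-squares problem in closed form at every node, and returns the node
#' and coefficients minimizing the weighted residual sum of squares. The
#' search is exhaustive and deterministic; RSS ties are broken toward
#' smaller td, then smaller Tc, then smaller k2.
#'
#' Physical constraints are enforced by clamping and re-solving: a negative
#' coefficient is fixed at 0 and the other refit; for AATH, nodes violating
#' the extraction bound `K1 <= F` are refit on the boundary `K1 = F`, and
#' nodes where the implied blood volume `F * Tc / 60` would exceed 1 are
#' capped. At `Tc = 0` the vascular regressor vanishes and F is not
#' identified; the convention `F = K1` (complete extraction) is reported.
#'
#' @param x A [tac()] on the basis's schedule.
#' @param basis A [build_basis()] result.
#' @param weights Optional explicit weight vector; by default taken from the
#'   basis grid's weighting scheme.
#' @return An object of class `fit_result`: fitted parameter object
#'   (`params`), named estimate vector (`estimates`), weighted `rss`, fitted
#'   TAC (`fitted`), selected grid `node` indices, frame count `n` and
#'   free-parameter count `k` (5 for AATH, 4 for S1TC).
#' @examples
#' aif <- generate_aif(aif_params())
#' sched <- htr_schedule()
#' truth <- aath_params(0.5, 0.14, 0.45, Tc = 4.5, td = 2)
#' basis <- build_basis(aif, sched, grid_config(), "aath")
#' fit <- fit_tac(forward_tac(truth, aif, sched), basis)
#' fit$estimates
#' @export
fit_tac <- function(x, basis, weights = NULL) {
  stopifnot(inherits(x, "tac"), inherits(basis, "kinetic_basis"))
  if (!schedules_equal(x$schedule, basis$schedule))
    stop("TAC schedule does not match the basis schedule")
  y <- x$values
  if (anyNA(y) || any(!is.finite(y))) stop("TAC contains non-finite values")

  if (is.null(weights)) {
    if (basis$grid$weighting == "inverse_variance") {
      w <- fit_weights(x, "inverse_variance")
    } else {
      w <- basis$w0
    }
  } else {
    if (length(weights) != length(y) || any(!is.finite(weights)) ||
        any(weights < 0))
      stop("'weights' must be a finite non-negative vector per frame")
    w <- weights
  }
  if (all(w == 0)) stop("all-zero weights")

  gram <- if (!is.null(basis$w0) && isTRUE(all.equal(w, basis$w0))) {
    basis$gram0
  } else {
    basis_gram(basis, w)
  }

  yw <- w * y
  u <- as.numeric(crossprod(basis$J, yw))
  v <- as.numeric(crossprod(basis$M, yw))
  if (basis$model == "aath") {
    b1 <- u[basis$n1] - u[basis$n2]
  } else {
    b1 <- u[basis$n1]
  }
  b2 <- v[basis$c2]

  sol <- solve_nodes(gram$G11, gram$G12, gram$G22, b1, b2,
                     model = basis$model, node_Tc = basis$node_Tc,
                     nonneg = basis$grid$nonneg)
  yty <- sum(w * y * y)
  rss <- yty - 2 * (sol$a1 * b1 + sol$a2 * b2) +
    sol$a1 * sol$a1 * gram$G11 + 2 * sol$a1 * sol$a2 * gram$G12 +
    sol$a2 * sol$a2 * gram$G22
  rss[rss < 0] <- 0
  best <- which.min(rss)

  nk <- basis$nk; nT <- basis$nT
  i <- (best - 1L) %% nk + 1L
  j <- ((best - 1L) %/% nk) %% nT + 1L
  l <- (best - 1L) %/% (nk * nT) + 1L
  a1 <- sol$a1[best]; a2 <- sol$a2[best]
  g <- basis$grid
  reg <- basis_regressors(basis, best)
  fitted_vals <- a1 * reg$x1 + a2 * reg$x2

  if (basis$model == "aath") {
    params <- aath_params_fit(a1, a2, g$k2[i], g$Tc[j], g$td[l])
    est <- c(F = a1, K1 = a2, k2 = g$k2[i], Tc = g$Tc[j], td = g$td[l],
             vb = a1 * g$Tc[j] / 60,
             E = if (a1 > 0) a2 / a1 else NA_real_)
    kfree <- 5L
    node <- c(k2 = i, Tc = j, td = l)
  } else {
    params <- s1tc_params(min(a1, 1), a2, g$k2[i], g$td[l])
    est <- c(vb = a1, K1 = a2, k2 = g$k2[i], td = g$td[l])
    kfree <- 4L
    node <- c(k2 = i, td = l)
  }
  structure(list(model = basis$model, params = params, estimates = est,
                 rss = rss[best], fitted = tac(x$schedule, fitted_vals,
                                              label = x$label),
                 node = node, n = length(y), k = kfree,
                 weights = w),
            class = "fit_result")
}

# Fitted AATH parameters may be degenerate (zero flow for an all-zero TAC),
# which the strict constructor rejects; build leniently here.
aath_params_fit <- function(flow, K1, k2, Tc, td) {
  if (flow > 0) {
    aath_params(flow, min(K1, flow), k2, Tc, td)
  } else {
    structure(list(flow = 0, K1 = 0, k2 = k2, Tc = Tc, td = td),
              class = "aath_params")
  }
}

# Vectorized constrained 2x2 weighted least squares across all grid nodes.
# Follows clamp-and-resolve: unconstrained solve, negative coefficients
# fixed at zero, then model-specific bounds (AATH: K1 <= F, F <= 60/Tc;
# S1TC: vb <= 1) via constrained refit on the active bound. Hot path:
# subset indexing throughout, no full-length conditional allocation.
solve_nodes <- function(G11, G12, G22, b1, b2, model, node_Tc, nonneg) {
  n <- length(b1)
  deg1 <- G11 <= 1e-12 * max(G11, 1e-300)
  deg2 <- G22 <= 1e-12 * max(G22, 1e-300)
  det <- G11 * G22 - G12 * G12
  ok <- det > 1e-10 * G11 * G22
  # guarded single-regressor solutions
  s1 <- numeric(n); s2 <- numeric(n)
  i <- which(!deg1); s1[i] <- b1[i] / G11[i]
  i <- which(!deg2); s2[i] <- b2[i] / G22[i]
  if (nonneg) { s1[s1 < 0] <- 0; s2[s2 < 0] <- 0 }

  a1 <- numeric(n)
  a2 <- s2  # default for collinear/degenerate nodes: x2 alone
  i <- which(ok)
  idet <- 1 / det[i]
  a1[i] <- (G22[i] * b1[i] - G12[i] * b2[i]) * idet
  a2[i] <- (G11[i] * b2[i] - G12[i] * b1[i]) * idet

  if (nonneg) {
    neg1 <- which(ok & a1 < 0)
    neg2 <- which(ok & a2 < 0)
    a1[neg1] <- 0; a2[neg1] <- s2[neg1]
    a2[neg2] <- 0; a1[neg2] <- s1[neg2]
    both <- intersect(neg1, neg2)
    a1[both] <- 0; a2[both] <- 0
  }

  if (model == "aath") {
    # extraction bound K1 <= F on the boundary K1 = F
    viol <- which(!deg1 & a2 > a1)
    if (length(viol)) {
      den <- G11[viol] + 2 * G12[viol] + G22[viol]
      aeq <- (b1[viol] + b2[viol]) / den
      aeq[den <= 1e-300] <- 0
      aeq[aeq < 0] <- 0
      a1[viol] <- aeq
      a2[viol] <- aeq
    }
    # Tc = 0: vascular regressor vanishes, report F = K1 (E = 1 convention)
    i <- which(deg1)
    a1[i] <- a2[i]
    # blood-volume bound F * Tc / 60 <= 1
    cap <- which(node_Tc > 0 & a1 * node_Tc > 60)
    if (length(cap)) {
      a1[cap] <- 60 / node_Tc[cap]
      k1c <- (b2[cap] - a1[cap] * G12[cap]) / G22[cap]
      k1c[deg2[cap]] <- 0
      a2[cap] <- pmin(pmax(k1c, 0), a1[cap])
    }
  } else {
    # blood-volume bound vb <= 1
    cap <- which(a1 > 1)
    if (length(cap)) {
      a1[cap] <- 1
      k1c <- (b2[cap] - G12[cap]) / G22[cap]
      k1c[deg2[cap]] <- 0
      a2[cap] <- pmax(k1c, 0)
    }
  }
  list(a1 = a1, a2 = a2)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, %d frames, weighted RSS %.6g\n",
              toupper(x$model), x$n, x$rss))
  print(round(x$estimates, 5))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$estimates
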