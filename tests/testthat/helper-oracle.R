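# Independent nonlinear least-squares refit used to cross-check the
# grid-search minimizer: multi-start Nelder-Mead over the nonlinear
# parameters with a closed-form constrained solve for the two linear
# coefficients at each evaluation (regressors obtained from unit-coefficient
# forward-model evaluations, not from the basis tables).

oracle_regressors <- function(model, k2, Tc, td, aif, sched) {
  if (model == "aath") {
    x1 <- forward_tac(aath_params(1, 0, k2, Tc, td), aif, sched)$values
    x12 <- forward_tac(aath_params(1, 1, k2, Tc, td), aif, sched)$values
    list(x1 = x1, x2 = x12 - x1)
  } else {
    list(x1 = forward_tac(s1tc_params(1, 0, k2, td), aif, sched)$values,
         x2 = forward_tac(s1tc_params(0, 1, k2, td), aif, sched)$values)
  }
}

oracle_inner <- function(y, w, r, model) {
  g11 <- sum(w * r$x1^2); g12 <- sum(w * r$x1 * r$x2); g22 <- sum(w * r$x2^2)
  b1 <- sum(w * r$x1 * y); b2 <- sum(w * r$x2 * y)
  det <- g11 * g22 - g12^2
  cand <- list(c(0, 0),
               c(max(b1 / max(g11, 1e-300), 0), 0),
               c(0, max(b2 / max(g22, 1e-300), 0)))
  if (det > 1e-12 * max(g11 * g22, 1e-300))
    cand <- c(cand, list(c((g22 * b1 - g12 * b2) / det,
                           (g11 * b2 - g12 * b1) / det)))
  if (model == "aath") {
    aeq <- max((b1 + b2) / max(g11 + 2 * g12 + g22, 1e-300), 0)
    cand <- c(cand, list(c(aeq, aeq)))
  }
  best <- Inf; ab <- c(0, 0)
  for (cc in cand) {
    feasible <- if (model == "aath") {
      cc[1] >= 0 && cc[2] >= 0 && cc[2] <= cc[1] + 1e-9
    } else {
      cc[1] >= 0 && cc[1] <= 1 && cc[2] >= 0
    }
    if (!feasible) next
    rss <- sum(w * (y - cc[1] * r$x1 - cc[2] * r$x2)^2)
    if (rss < best) { best <- rss; ab <- cc }
  }
  list(rss = best, ab = ab)
}

oracle_refit <- function(x, aif, model = "aath", weights = NULL) {
  y <- x$values
  w <- if (is.null(weights)) fit_weights(x, "frame_duration") else weights
  sched <- x$schedule
  if (model == "aath") {
    obj <- function(p) {
      oracle_inner(y, w, oracle_regressors("aath", exp(p[1]),
                                           max(p[2], 0), max(p[3], 0),
                                           aif, sched), "aath")$rss
    }
    starts <- list(c(log(0.1), 3, 1), c(log(0.5), 8, 4), c(log(1.5), 15, 8))
  } else {
    obj <- function(p) {
      oracle_inner(y, w, oracle_regressors("s1tc", exp(p[1]), 0,
                                           max(p[2], 0), aif, sched),
                   "s1tc")$rss
    }
    starts <- list(c(log(0.1), 1), c(log(0.5), 4), c(log(1.5), 8))
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- best$par
  if (model == "aath") {
    r <- oracle_regressors("aath", exp(p[1]), max(p[2], 0), max(p[3], 0),
                           aif, sched)
    inner <- oracle_inner(y, w, r, "aath")
    list(rss = inner$rss, flow = inner$ab[1], K1 = inner$ab[2],
         k2 = exp(p[1]), Tc = max(p[2], 0), td = max(p[3], 0))
  } else {
    r <- oracle_regressors("s1tc", exp(p[1]), 0, max(p[2], 0), aif, sched)
    inner <- oracle_inner(y, w, r, "s1tc")
    list(rss = inner$rss, vb = inner$ab[1], K1 = inner$ab[2],
         k2 = exp(p[1]), td = max(p[2], 0))
  }
}
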