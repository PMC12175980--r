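test_that("frame schedules enforce ordering and the HTR protocol constant", {
  s <- htr_schedule()
  expect_equal(n_frames(s), 90)
  expect_equal(frame_durations(s), c(rep(1, 60), rep(2, 30)))
  expect_equal(s$starts[1], 0)
  expect_equal(s$ends[90], 120)

  expect_error(frame_schedule(0, 1), "at least 2")
  expect_error(frame_schedule(c(0, 1), c(1, 0.5)), "exceed its start")
  expect_error(frame_schedule(c(0, 0.5), c(1, 1.5)), "non-overlapping")
  expect_error(frame_schedule(c(-1, 1), c(1, 2)), "non-negative")
})

test_that("TAC and arterial input containers validate their invariants", {
  s <- htr_schedule()
  expect_error(tac(s, 1:89), "length")
  expect_error(tac(s, c(rep(1, 89), NA)), "finite")
  expect_error(arterial_input(seq(0, 10, 1), rep(1, 11)), "at most 0.5")
  expect_error(arterial_input(c(0, 0.1, 0.3), rep(1, 3)), "uniform")
  expect_error(arterial_input(seq(0, 1, 0.1), c(rep(1, 10), -1)),
               "non-negative")
})

test_that("impulse responses match their case-split definitions", {
  ps <- s1tc_params(vb = 0.05, K1 = 0.2, k2 = 0.693)
  expect_equal(s1tc_irf(0, ps), 0.05)
  expect_equal(s1tc_irf(60, s1tc_params(0.05, 0.2, 0)), 0.2)
  expect_equal(s1tc_irf(60, ps), 0.2 * exp(-0.693), tolerance = 1e-12)
  expect_equal(s1tc_irf(60, ps), 0.1, tolerance = 1e-3)
  expect_error(s1tc_irf(-1, ps), ">= 0")

  pa <- aath_params(flow = 0.6, K1 = 0.2, k2 = 0.693, Tc = 5)
  expect_equal(aath_irf(2, pa), 0.6)           # vascular phase
  expect_equal(aath_irf(5, pa), 0.2)           # right-continuous at Tc
  expect_equal(aath_irf(65, pa), 0.2 * exp(-0.693), tolerance = 1e-12)
  expect_equal(aath_irf(30, aath_params(0.6, 0.2, 0, Tc = 0)), 0.2)
  expect_error(aath_irf(-0.1, pa), ">= 0")
})

test_that("derived-quantity identities hold with unit conversion", {
  expect_equal(extraction_fraction(1, 1), 1)
  expect_equal(extraction_fraction(0.507, 0.136), 0.136 / 0.507)
  expect_equal(extraction_fraction(0.507, 0.136), 0.2682, tolerance = 1e-3)
  expect_equal(extraction_fraction(2, 0), 0)
  expect_error(extraction_fraction(1, 1.5), "K1")
  expect_error(extraction_fraction(0, 0), "flow")

  expect_equal(vascular_transit_time(0.05, 1), 3)
  expect_equal(vascular_transit_time(0, 1), 0)
  expect_equal(vascular_transit_time(0.036, 0.507), 4.26, tolerance = 0.002)
  expect_error(vascular_transit_time(0.05, 0), "flow")

  expect_error(aath_params(0.5, 0.6, 0.3, 5), "extraction")
})

test_that("forward model is linear in the linear coefficients", {
  aif <- fx_aif(); s <- fx_sched()
  q0 <- forward_tac(aath_params(0.4, 0.1, 0.5, Tc = 6, td = 3), aif, s)
  qF <- forward_tac(aath_params(0.8, 0.1, 0.5, Tc = 6, td = 3), aif, s)
  qK <- forward_tac(aath_params(0.4, 0.2, 0.5, Tc = 6, td = 3), aif, s)
  # doubling F doubles the vascular component; superposition reconstructs
  q2 <- forward_tac(aath_params(0.8, 0.2, 0.5, Tc = 6, td = 3), aif, s)
  expect_equal(q2$values, qF$values + qK$values - q0$values,
               tolerance = 1e-12)

  ps0 <- forward_tac(s1tc_params(0.03, 0.1, 0.5, td = 3), aif, s)
  psv <- forward_tac(s1tc_params(0.06, 0.1, 0.5, td = 3), aif, s)
  psk <- forward_tac(s1tc_params(0.03, 0.2, 0.5, td = 3), aif, s)
  ps2 <- forward_tac(s1tc_params(0.06, 0.2, 0.5, td = 3), aif, s)
  expect_equal(ps2$values, psv$values + psk$values - ps0$values,
               tolerance = 1e-12)
})

test_that("forward model handles degenerate inputs", {
  s <- fx_sched()
  zero_aif <- arterial_input(seq(0, 180, 0.5), rep(0, 361))
  q <- forward_tac(aath_params(0.5, 0.2, 0.5, Tc = 5, td = 2), zero_aif, s)
  expect_equal(q$values, rep(0, 90))
  # insufficient AIF coverage
  short_aif <- arterial_input(seq(0, 60, 0.5), rep(1, 121))
  expect_error(forward_tac(aath_params(0.5, 0.2, 0.5, Tc = 5), short_aif, s),
               "cover")
})

test_that("non-negative AIF and valid parameters give a non-negative TAC", {
  aif <- fx_aif(); s <- fx_sched()
  set.seed(42)
  for (i in 1:20) {
    p <- random_aath_truth(fx_grid())
    expect_true(all(forward_tac(p, aif, s)$values >= -1e-12))
  }
})

test_that("time-shift equivariance: AIF shift offsets the fitted delay", {
  s <- fx_sched()
  aif <- fx_aif()
  delta <- 4
  shifted <- arterial_input(aif$times,
                            c(rep(0, delta / aif$dt),
                              aif$values[1:(length(aif$values) - delta / aif$dt)]))
  p_base <- aath_params(0.5, 0.15, 0.4, Tc = 5, td = 6)
  p_less <- aath_params(0.5, 0.15, 0.4, Tc = 5, td = 2)
  q1 <- forward_tac(p_base, aif, s)
  q2 <- forward_tac(p_less, shifted, s)
  expect_equal(q1$values, q2$values, tolerance = 1e-9)
})

test_that("Tc -> 0 AATH limit converges to the S1TC curve at fixed vb", {
  aif <- fx_aif(); s <- fx_sched()
  vb <- 0.04; K1 <- 0.12; k2 <- 0.5
  ps <- forward_tac(s1tc_params(vb, K1, k2, td = 2), aif, s)
  err <- vapply(c(0.2, 0.05, 0.02), function(Tc) {
    pa <- forward_tac(aath_params(60 * vb / Tc, K1, k2, Tc = Tc, td = 2),
                      aif, s)
    max(abs(pa$values - ps$values)) / max(ps$values)
  }, 0)
  # converges up to the half-sample offset of the discrete vascular-phase
  # derivative (fine grid 0.1 s), i.e. to grid-spacing tolerance
  expect_lt(err[3], 0.02)
  expect_true(all(diff(err) < 0))  # error shrinks with Tc
})

test_that("constant-input plateau equals c * (vb + K1/k2)", {
  # long constant infusion; exponential fully equilibrated by the last frame
  sched <- frame_schedule(seq(0, 298, 2), seq(2, 300, 2))
  cval <- 10
  aif <- arterial_input(seq(0, 300, 0.5), rep(cval, 601))
  vb <- 0.05; K1 <- 0.2; k2 <- 2
  qa <- forward_tac(aath_params(60 * vb / 4, K1, k2, Tc = 4), aif, sched)
  qs <- forward_tac(s1tc_params(vb, K1, k2), aif, sched)
  plateau <- cval * (vb + K1 / k2)
  expect_equal(tail(qa$values, 1), plateau, tolerance = 1e-3)
  expect_equal(tail(qs$values, 1), plateau, tolerance = 1e-3)
})

test_that("TAC and AIF tables round-trip through delimited text", {
  s <- htr_schedule()
  x <- tac(s, rexp(90), label = "cortical_gm")
  f <- tempfile(fileext = ".tsv")
  write_tac_table(list(cortical_gm = x), f)
  back <- read_tac_table(f)
  expect_equal(back$cortical_gm$values, x$values, tolerance = 1e-9)
  expect_equal(back$cortical_gm$label, "cortical_gm")

  aif <- fx_aif()
  fa <- tempfile(fileext = ".tsv")
  write_aif_table(aif, fa)
  back <- read_aif_table(fa)
  expect_equal(back$values, aif$values, tolerance = 1e-9)
})
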