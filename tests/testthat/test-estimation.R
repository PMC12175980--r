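test_that("fit weights implement the three schemes", {
  s <- htr_schedule()
  x <- tac(s, rep(5, 90))
  expect_equal(fit_weights(x, "uniform"), rep(1, 90))
  expect_equal(fit_weights(x, "frame_duration"), c(rep(1, 60), rep(2, 30)))
  expect_equal(fit_weights(x, "inverse_variance"),
               c(rep(1, 60), rep(2, 30)) / 5)
  expect_error(fit_weights(x, "bogus"))
})

test_that("degenerate basis nodes reduce to their analytic forms", {
  aif <- fx_aif(); s <- fx_sched()
  g <- grid_config(k2 = c(1e-8, 0.5), Tc = c(0, 5), td = c(0, 2))
  b <- build_basis(aif, s, g, "aath")
  # Tc = 0: vascular regressor identically zero, tissue regressor matches
  # the S1TC convolution regressor
  node_tc0 <- which(b$node_Tc == 0)[1]
  r <- aathflow:::basis_regressors(b, node_tc0)
  expect_equal(r$x1, rep(0, 90))
  bs <- build_basis(aif, s, grid_config(k2 = c(1e-8, 0.5), td = c(0, 2)),
                    "s1tc")
  rs <- aathflow:::basis_regressors(bs, 1)  # td = 0, k2 = 1e-8
  expect_equal(r$x2, rs$x2, tolerance = 1e-12)
  # k2 ~ 0: tissue regressor equals the running integral of the delayed AIF
  t_end <- 120
  ca <- aathflow:::resample_aif(aif, t_end)
  A <- aathflow:::frame_avg_matrix(s, length(ca))
  running <- as.numeric(A %*% (aathflow:::cumtrapz_fine(ca) / 60))
  expect_equal(rs$x2, running, tolerance = 1e-6)
})

test_that("noiseless on-grid AATH and S1TC TACs are recovered exactly", {
  set.seed(11)
  g <- fx_grid()
  ba <- fx_basis("aath"); bs <- fx_basis("s1tc")
  for (i in 1:5) {
    tr <- random_aath_truth(g)
    q <- forward_tac(tr, fx_aif(), fx_sched())
    fit <- fit_tac(q, ba)
    expect_equal(fit$estimates[["F"]], tr$flow, tolerance = 1e-6)
    expect_equal(fit$estimates[["K1"]], tr$K1, tolerance = 1e-6)
    expect_equal(fit$estimates[["k2"]], tr$k2, tolerance = 1e-9)
    expect_equal(fit$estimates[["Tc"]], tr$Tc, tolerance = 1e-9)
    expect_equal(fit$estimates[["td"]], tr$td, tolerance = 1e-9)
    expect_lt(fit$rss / sum(fit$weights * q$values^2), 1e-12)

    trs <- random_s1tc_truth(g)
    qs <- forward_tac(trs, fx_aif(), fx_sched())
    fits <- fit_tac(qs, bs)
    expect_equal(fits$estimates[["vb"]], trs$vb, tolerance = 1e-6)
    expect_equal(fits$estimates[["K1"]], trs$K1, tolerance = 1e-6)
    expect_equal(fits$estimates[["k2"]], trs$k2, tolerance = 1e-9)
    expect_equal(fits$estimates[["td"]], trs$td, tolerance = 1e-9)
  }
})

test_that("an all-zero TAC fits to zero coefficients with zero RSS", {
  z <- tac(fx_sched(), rep(0, 90))
  fit <- fit_tac(z, fx_basis("aath"))
  expect_equal(fit$estimates[["F"]], 0)
  expect_equal(fit$estimates[["K1"]], 0)
  expect_equal(fit$rss, 0)
  fits <- fit_tac(z, fx_basis("s1tc"))
  expect_equal(fits$estimates[["vb"]], 0)
  expect_equal(fits$estimates[["K1"]], 0)
})

test_that("grid refinement never increases the optimal RSS", {
  aif <- fx_aif(); s <- fx_sched()
  tr <- aath_params(0.5, 0.15, 0.37, Tc = 4.7, td = 1.7)  # off-grid
  q <- forward_tac(tr, aif, s)
  coarse <- grid_config(k2 = exp(seq(log(0.05), log(1), length.out = 6)),
                        Tc = seq(0, 10, 2), td = seq(0, 4, 2))
  fine <- grid_config(k2 = exp(seq(log(0.05), log(1), length.out = 11)),
                      Tc = seq(0, 10, 1), td = seq(0, 4, 1))
  rss_c <- fit_tac(q, build_basis(aif, s, coarse, "aath"))$rss
  rss_f <- fit_tac(q, build_basis(aif, s, fine, "aath"))$rss
  expect_lte(rss_f, rss_c + 1e-12)
})

test_that("joint TAC/AIF rescaling leaves rates and times unchanged", {
  aif <- fx_aif(); s <- fx_sched(); g <- small_grid()
  tr <- aath_params(0.6, 0.2, 0.3, Tc = 5, td = 2)
  q <- forward_tac(tr, aif, s)
  fit1 <- fit_tac(q, build_basis(aif, s, g, "aath"))
  sc <- 3.7
  aif2 <- arterial_input(aif$times, sc * aif$values)
  q2 <- tac(s, sc * q$values)
  fit2 <- fit_tac(q2, build_basis(aif2, s, g, "aath"))
  expect_equal(fit1$estimates[c("F", "K1", "k2", "Tc", "td")],
               fit2$estimates[c("F", "K1", "k2", "Tc", "td")],
               tolerance = 1e-8)
})

test_that("fitted AATH parameters always satisfy the physical bounds", {
  set.seed(19)
  aif <- fx_aif(); s <- fx_sched()
  ba <- fx_basis("aath")
  for (i in 1:15) {
    tr <- random_aath_truth(fx_grid())
    clean <- forward_tac(tr, aif, s)
    nz <- noise_config(calibrate_noise_scale(clean, 10))  # heavy noise
    noisy <- aathflow:::add_tac_noise(clean, nz)
    est <- fit_tac(noisy, ba)$estimates
    expect_gte(est[["K1"]], 0)
    expect_lte(est[["K1"]], est[["F"]] + 1e-9)
    expect_gte(est[["vb"]], 0)
    expect_lte(est[["vb"]], 1)
    if (est[["F"]] > 0) {
      expect_gte(est[["E"]], 0)
      expect_lte(est[["E"]], 1 + 1e-9)
    }
  }
})

test_that("fit rejects malformed input", {
  ba <- fx_basis("aath")
  bad <- tac(fx_sched(), rep(1, 90))
  bad$values[5] <- NaN
  expect_error(fit_tac(bad, ba), "non-finite")
  expect_error(fit_tac(tac(fx_sched(), rep(1, 90)), ba,
                       weights = rep(0, 90)), "all-zero")
  other <- frame_schedule(seq(0, 118, 2), seq(2, 120, 2))
  expect_error(fit_tac(tac(other, rep(1, 60)), ba), "schedule")
})

test_that("grid config files mirror grid_config field-for-field", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("k2: [0.1, 0.5, 1.0]", "Tc: [0, 2, 4]", "td: [0, 1]",
               "weighting: uniform"), f)
  g <- read_grid_config(f)
  expect_equal(g$k2, c(0.1, 0.5, 1))
  expect_equal(g$weighting, "uniform")
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(k2 = c(0.2, 0.9), Tc = c(0, 5), td = c(0, 2)),
                       fj, auto_unbox = FALSE)
  gj <- read_grid_config(fj)
  expect_equal(gj$k2, c(0.2, 0.9))
  writeLines("bogus_field: 3", f)
  expect_error(read_grid_config(f), "unknown")
})
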