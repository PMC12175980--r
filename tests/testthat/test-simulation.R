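test_that("regional presets carry the reference early-kinetics values", {
  d <- region_presets()
  expect_equal(nrow(d), 10)
  gm <- d[d$region == "cortical_gm", ]
  expect_equal(gm$flow, 0.507)
  expect_equal(gm$K1, 0.136)
  expect_equal(gm$vb, 0.036)
  expect_equal(gm$Tc, 4.4)
  mus <- d[d$region == "skeletal_muscle", ]
  expect_equal(mus$flow, 0.039)
  expect_equal(mus$Tc, 29.1)
  lng <- d[d$region == "lungs", ]
  expect_equal(lng$flow, 2.031)
  expect_equal(lng$vb, 0.143)
  expect_equal(lng$K1, 0.072)  # cohort median
  expect_equal(lng$input_source, "right_ventricle")
  expect_equal(d$k2, d$K1 / unname(default_region_vd()))
  expect_true(all(d$k2 > 0 & d$k2 < 3))  # inside the physiologic range
  expect_equal(region_presets(vd = 0.5)$k2, d$K1 / 0.5)
  # every preset satisfies the AATH parameter invariants
  for (r in d$region) expect_s3_class(preset_params(r), "aath_params")
})

test_that("simulated noise is seeded, scaled, and law-abiding", {
  p <- preset_params("cortical_gm")
  aif <- fx_aif(); s <- fx_sched()
  clean <- forward_tac(p, aif, s)

  expect_equal(simulate_tac(p, aif, s, noise_config(0))$values, clean$values)
  a <- simulate_tac(p, aif, s, noise_config(0.05, seed = 9))
  b <- simulate_tac(p, aif, s, noise_config(0.05, seed = 9))
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_tac(p, aif, s, noise_config(0.05, seed = 10))$values))

  # empirical per-frame SD matches the variance law
  nz <- noise_config(0.1)
  set.seed(2)
  reps <- replicate(10000, aathflow:::add_tac_noise(clean, nz)$values)
  emp_sd <- apply(reps, 1, sd)
  expected <- aathflow:::noise_sd(clean$values, frame_durations(s), nz)
  expect_lt(max(abs(emp_sd - expected) / expected), 0.05)
})

test_that("noise scale calibration hits the target peak SNR", {
  clean <- forward_tac(preset_params("cortical_gm"), fx_aif(), fx_sched())
  sc <- calibrate_noise_scale(clean, 25)
  p <- which.max(clean$values)
  sd_pk <- aathflow:::noise_sd(clean$values, frame_durations(fx_sched()),
                               noise_config(sc))[p]
  expect_equal(clean$values[p] / sd_pk, 25, tolerance = 1e-9)
})

test_that("identifiability analysis recovers noiseless truth and is seeded", {
  d <- region_presets()[c(1, 7), ]
  rep1 <- identifiability_analysis(d, fx_aif(), n_reps = 2, peak_snr = 1e9,
                                   grid = fx_grid(), seed = 4)
  # near-zero noise: bias limited to grid quantization (Tc step 0.5 s and
  # the ~12% geometric k2 step around off-grid truth), spread vanishes
  f_err <- rep1[rep1$parameter == "F", ]
  expect_lt(max(abs(f_err$mean_pct_error)), 3)
  expect_lt(max(f_err$sd_pct_error), 1e-6)
  tc_err <- rep1[rep1$parameter == "Tc", ]
  expect_lt(max(abs(tc_err$mean_pct_error)), 100 * 0.5 / 4.4)
  expect_true(all(rep1$n_reps == 2))
  rep2 <- identifiability_analysis(d, fx_aif(), n_reps = 2, peak_snr = 1e9,
                                   grid = fx_grid(), seed = 4)
  expect_equal(rep1$mean_pct_error, rep2$mean_pct_error)
})

test_that("raising the noise does not shrink percent-error spread", {
  d <- region_presets()[1, , drop = FALSE]
  g <- fx_grid()
  lo <- identifiability_analysis(d, fx_aif(), n_reps = 25, peak_snr = 50,
                                 grid = g, seed = 6)
  hi <- identifiability_analysis(d, fx_aif(), n_reps = 25, peak_snr = 10,
                                 grid = g, seed = 6)
  expect_gte(hi[hi$parameter == "F", "sd_pct_error"],
             lo[lo$parameter == "F", "sd_pct_error"])
})

test_that("noiseless phantoms reproduce regional forward curves exactly", {
  lab <- phantom_label_map()
  ph <- simulate_phantom(lab, aifs = fx_aif(), seed = 1)
  for (r in c(1, 6, 10)) {
    p <- region_presets()[r, ]
    clean <- forward_tac(aath_params(p$flow, p$K1, p$k2, p$Tc, td = 2),
                         fx_aif(), fx_sched())
    rt <- extract_roi_tac(ph, lab == r)
    expect_equal(rt$values, clean$values, tolerance = 1e-12)
    # every voxel individually equals the regional curve
    vox <- which(lab == r, arr.ind = TRUE)[1, ]
    expect_equal(as.numeric(ph$data[vox[1], vox[2], vox[3], ]),
                 clean$values, tolerance = 1e-12)
  }
  expect_error(simulate_phantom(array(11L, dim = c(24, 24, 24))), "labels")
})

test_that("noisy phantom region means converge to the forward curve", {
  lab <- array(0L, dim = c(24, 24, 24))
  lab[1:10, 1:10, 1:10] <- 1L  # 1000 voxels
  p <- region_presets()[1, ]
  clean <- forward_tac(aath_params(p$flow, p$K1, p$k2, p$Tc, td = 2),
                       fx_aif(), fx_sched())
  nz <- noise_config(calibrate_noise_scale(clean, 25))
  ph <- simulate_phantom(lab, aifs = fx_aif(), noise = nz, seed = 12)
  m <- extract_roi_tac(ph, lab == 1)$values
  # per-frame mean of 1000 voxels: SE is ~1/sqrt(1000) of the voxel SD
  sds <- aathflow:::noise_sd(clean$values, frame_durations(fx_sched()), nz)
  expect_lt(max(abs(m - clean$values) / (sds / sqrt(1000))), 5)
})
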