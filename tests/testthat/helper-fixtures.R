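# Shared fixtures, memoized across test files (basis construction is the
# expensive step and is identical wherever the default grid is used).

.fx <- new.env(parent = emptyenv())

fx_aif <- function() {
  if (is.null(.fx$aif)) .fx$aif <- generate_aif(aif_params())
  .fx$aif
}

fx_aif_rv <- function() {
  if (is.null(.fx$aif_rv))
    .fx$aif_rv <- generate_aif(aif_params(site = "right_ventricle"))
  .fx$aif_rv
}

fx_sched <- function() {
  if (is.null(.fx$sched)) .fx$sched <- htr_schedule()
  .fx$sched
}

fx_grid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- grid_config()
  .fx$grid
}

fx_basis <- function(model = "aath") {
  key <- paste0("basis_", model)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- build_basis(fx_aif(), fx_sched(), fx_grid(), model)
  .fx[[key]]
}

# compact grid for cheap structural tests
small_grid <- function() {
  grid_config(k2 = exp(seq(log(0.02), log(2), length.out = 12)),
              Tc = seq(0, 12, by = 1),
              td = seq(0, 6, by = 1))
}

# random on-grid AATH / S1TC truths (linear coefficients continuous)
random_aath_truth <- function(grid) {
  k2 <- sample(grid$k2, 1)
  Tc <- sample(grid$Tc[grid$Tc >= 2 & grid$Tc <= 30], 1)
  td <- sample(grid$td[grid$td <= 10], 1)
  flow <- stats::runif(1, 0.1, 2)
  E <- stats::runif(1, 0.1, 0.9)
  aath_params(flow, E * flow, k2, Tc, td)
}

random_s1tc_truth <- function(grid) {
  s1tc_params(stats::runif(1, 0.01, 0.3), stats::runif(1, 0.05, 1),
              sample(grid$k2, 1), sample(grid$td[grid$td <= 10], 1))
}
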