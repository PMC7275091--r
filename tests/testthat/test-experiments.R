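test_that("aggregation uses linear-interpolation percentiles", {
  d <- tibble::tibble(K_ext = 1, v = 1:100)
  agg <- aggregate_metrics(d, K_ext, values = "v")
  expect_equal(agg$v_median, 50.5)
  expect_equal(agg$v_q05, 5.95)
  expect_equal(agg$v_q95, 95.05)
  # degenerate cells
  d1 <- tibble::tibble(K_ext = 1, v = 7)
  a1 <- aggregate_metrics(d1, K_ext, values = "v")
  expect_equal(c(a1$v_median, a1$v_q05, a1$v_q95), c(7, 7, 7))
  dd <- tibble::tibble(K_ext = 1, v = rep(3, 10))
  ad <- aggregate_metrics(dd, K_ext, values = "v")
  expect_equal(ad$v_q95 - ad$v_q05, 0)
})

test_that("re-equilibration time logic", {
  sn <- tibble::tibble(time_s = 1:20,
                       m = c(rep(2, 5), rep(0.5, 3), 2, rep(0.5, 11)))
  expect_equal(reequilibration_time(sn, 0.4, 0.6, hold = 10), 10)
  expect_equal(reequilibration_time(sn, 0.4, 0.6, hold = 3), 6)
  expect_true(is.na(reequilibration_time(sn, 0.9, 1.1, hold = 3)))
})

test_that("branching snapshots cover the run in 1-s windows", {
  cfg <- network_config(K_ext = 8, gamma_v = 1)
  topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 60)
  stim <- poisson_stimulus(cfg, 5000, seed = 61)
  w <- matrix(150, cfg$N, cfg$N)
  sim <- simulate_network(topo, cfg, stim, w_init = w, seed = 62)
  sn <- branching_snapshots(sim$spikes, cfg)
  expect_equal(nrow(sn), 5)
  expect_true(all(is.finite(sn$m)))
})

test_that("sweep isolates failing cells instead of aborting", {
  cfg <- network_config()
  # zero-duration burn-in with zero weights gives silent frozen runs:
  # analysis degenerates but the sweep keeps going
  expect_warning(
    out <- run_kext_sweep(cfg, K_grid = c(8), seeds = 1,
                          T_burnin = 1000, T_exp = 1000),
    NA
  )
  expect_equal(nrow(out), 1)
  expect_true("rate_hz" %in% names(out) || "burnin_rate_hz" %in% names(out))
})

test_that("run metadata survives the raster/weights round trip", {
  cfg <- network_config(K_ext = 9)
  topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 63)
  stim <- poisson_stimulus(cfg, 1000, seed = 64)
  sim <- simulate_network(topo, cfg, stim, w_init = matrix(120, 32, 32),
                          seed = 65)
  tf <- tempfile(fileext = ".tsv")
  write_raster(sim$spikes, tf)
  back <- read_raster(tf)
  expect_equal(back$unit, sim$spikes$unit)
  expect_equal(back$time_ms, sim$spikes$time_ms)
  expect_equal(raster_duration(back), 1000)

  wf <- tempfile(fileext = ".tsv")
  write_weights(sim$w_final, topo, wf, seeds = list(stimulus = 64))
  wb <- read_weights(wf)
  expect_equal(wb$w, sim$w_final, tolerance = 1e-12)
  expect_identical(wb$topology$ext, topo$ext)
  expect_equal(wb$seeds$stimulus, 64)

  cf <- tempfile(fileext = ".yaml")
  write_config(cfg, cf)
  cfg2 <- read_config(cf)
  expect_equal(cfg2$K_ext, 9L)
  expect_equal(cfg2$g_leak, cfg$g_leak)
})
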