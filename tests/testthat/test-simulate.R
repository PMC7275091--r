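# closed-form LIF response to one delta-current input: peak deflection factor
# (tau_s/(tau_s - tau_m)) * ((tau_m/tau_s)^(tau_m/(tau_s-tau_m)) -
#  (tau_m/tau_s)^(tau_s/(tau_s-tau_m))) evaluated via the peak time
peak_factor <- function(tau_s, tau_m) {
  tstar <- tau_s * tau_m / (tau_s - tau_m) * log(tau_s / tau_m)
  tau_s / (tau_s - tau_m) * (exp(-tstar / tau_s) - exp(-tstar / tau_m))
}

one_spike_setup <- function(w_scale) {
  cfg <- network_config(N = 4L, K_ext = 4L, N_inh = 0L, gamma_v = 1)
  topo <- build_topology(4, K_ext = 4, N_inh = 0, seed = 1)
  stim <- new_raster(1L, 10, "stim", 200)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w_scale
  list(cfg = cfg, topo = topo, stim = stim, w = w)
}

test_that("single input spike fires iff the closed-form peak crosses threshold", {
  pf <- peak_factor(3.7, 1.6)
  w_th <- (554 - 384) / pf  # minimal weight for a single-spike crossing
  sup <- one_spike_setup(1.3 * w_th)
  sim <- simulate_network(sup$topo, sup$cfg, sup$stim, duration = 200,
                          w_init = sup$w, seed = 1)
  expect_equal(nrow(sim$spikes), 1L)
  expect_equal(sim$spikes$unit, 2L)
  expect_gte(sim$spikes$time_ms, 10 + sup$cfg$d_syn)
  sub <- one_spike_setup(0.8 * w_th)
  sim2 <- simulate_network(sub$topo, sub$cfg, sub$stim, duration = 200,
                           w_init = sub$w, seed = 1)
  expect_equal(nrow(sim2$spikes), 0L)
})

test_that("membrane relaxes to the leak potential without input", {
  cfg <- network_config(N = 2L, K_ext = 2L, N_inh = 0L)
  topo <- build_topology(2, 2, 0, seed = 1)
  sim <- simulate_network(topo, cfg, stimulus = NULL, duration = 50,
                          w_init = matrix(0, 2, 2), record_u = TRUE,
                          seed = 1)
  expect_equal(nrow(sim$spikes), 0L)
  expect_true(all(abs(sim$u_trace - cfg$u_leak) < 1e-9))
})

test_that("identical seeds give bit-identical rasters and weights", {
  cfg <- network_config(K_ext = 10)
  topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 5)
  stim <- poisson_stimulus(cfg, 5000, seed = 6)
  s1 <- simulate_network(topo, cfg, stim, plasticity = TRUE, seed = 7)
  s2 <- simulate_network(topo, cfg, stim, plasticity = TRUE, seed = 7)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$w_final, s2$w_final)
  s3 <- simulate_network(topo, cfg, stim, plasticity = TRUE, seed = 8)
  expect_false(identical(s3$w_final, s1$w_final))
})

test_that("no neuron fires twice within the refractory period", {
  cfg <- network_config(K_ext = 8, gamma_v = 1)
  topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 2)
  stim <- poisson_stimulus(cfg, 3000, seed = 3)
  w <- matrix(200, cfg$N, cfg$N)  # strong weights: dense firing
  sim <- simulate_network(topo, cfg, stim, w_init = w, seed = 4)
  expect_gt(nrow(sim$spikes), 100)
  isi <- sim$spikes %>%
    dplyr::group_by(unit) %>%
    dplyr::summarise(min_isi = min(diff(time_ms), Inf), .groups = "drop")
  expect_true(all(isi$min_isi >= cfg$tau_ref - 1e-9))
})

test_that("production core matches the independent reference integrator", {
  # decisive (strong, sparse) weights keep every threshold crossing far from
  # the floating-point margin, so the two integrators must agree spike for
  # spike; counts are compared at the +-1 contract.
  cnt <- function(r, n) tabulate(r$unit, n)
  cfg <- network_config(N = 16L, K_ext = 16L, N_inh = 3L, gamma_v = 1)
  topo <- build_topology(16, 16, 3, seed = 11)
  stim <- poisson_stimulus(cfg, 10e3, seed = 12)
  set.seed(13)
  w <- matrix(500 * rbinom(256, 1, 0.3), 16, 16)
  sim <- simulate_network(topo, cfg, stim, w_init = w, seed = 1)
  ref <- ref_simulate(topo, cfg, stim, 10e3, w)
  expect_gt(nrow(sim$spikes), 500)
  expect_true(all(abs(cnt(sim$spikes, 16) - cnt(ref, 16)) <= 1))

  # recurrent network, shorter run
  cfg2 <- network_config(N = 16L, K_ext = 6L, N_inh = 3L, gamma_v = 1)
  topo2 <- build_topology(16, 6, 3, seed = 21)
  stim2 <- poisson_stimulus(cfg2, 3e3, seed = 22)
  set.seed(23)
  w2 <- matrix(450 * rbinom(256, 1, 0.25), 16, 16)
  sim2 <- simulate_network(topo2, cfg2, stim2, w_init = w2, seed = 1)
  ref2 <- ref_simulate(topo2, cfg2, stim2, 3e3, w2)
  expect_gt(nrow(sim2$spikes), 100)
  expect_true(all(abs(cnt(sim2$spikes, 16) - cnt(ref2, 16)) <= 1))
})

test_that("dt incompatible with the synaptic delay is rejected", {
  cfg <- network_config(dt = 0.3)
  topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 1)
  expect_error(simulate_network(topo, cfg, duration = 100), "multiple of dt")
})

test_that("burn-in returns zero matrices for zero duration and is reproducible", {
  cfg <- network_config(K_ext = 10)
  b0 <- burn_in(cfg, duration = 0, seeds = 1:2)
  expect_true(all(vapply(b0$w, function(m) all(m == 0), TRUE)))
  b1 <- burn_in(cfg, duration = 3000, seeds = 1)
  b2 <- burn_in(cfg, duration = 3000, seeds = 1)
  expect_identical(b1$w[[1]], b2$w[[1]])
})

test_that("halving the integration step preserves the post-burn-in rate", {
  rate_at <- function(dt) {
    cfg <- network_config(K_ext = 16, dt = dt)
    topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 31)
    stim <- poisson_stimulus(cfg, 625e3, seed = 32)
    sim <- simulate_network(topo, cfg, stim, plasticity = TRUE, seed = 33)
    late <- sim$spikes$time_ms >= 625e3 * 2 / 3
    sum(late) / cfg$N / (625 / 3)
  }
  r1 <- rate_at(0.1)
  r2 <- rate_at(0.05)
  expect_lt(abs(r2 - r1) / r1, 0.05)
})
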