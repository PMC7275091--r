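test_that("branching-ratio regression recovers AR(1) parameters", {
  set.seed(14)
  for (m in c(0.5, 0.9, 0.99)) {
    a <- ref_branching_series(1e5, m, h = 5 * (1 - m) + 0.5)
    est <- estimate_branching_ratio(a, binwidth = 5)
    # within 3 standard errors of the regression
    se <- sqrt((1 - m^2) / length(a))  # AR(1) slope standard error scale
    expect_lt(abs(est$m - m), max(3 * se, 0.01))
  }
})

test_that("iid activity has branching ratio near zero", {
  set.seed(15)
  est <- estimate_branching_ratio(rpois(5e4, 5), binwidth = 5)
  expect_lt(abs(est$m), 0.02)
})

test_that("branching timescale identities", {
  expect_equal(branching_timescale(exp(-1), 5), 5)
  expect_equal(branching_timescale(1, 5), Inf)
  expect_equal(branching_timescale(1.2, 5), Inf)
  expect_true(is.na(branching_timescale(-0.1, 5)))
  # strictly increasing in m on (0, 1)
  ms <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(branching_timescale(ms, 5)) > 0))
  expect_error(estimate_branching_ratio(rep(4, 100), binwidth = 5),
               "constant")
})

test_that("autocorrelation time matches the AR(1) closed form", {
  set.seed(16)
  a <- ref_branching_series(2e5, 0.9, h = 2)
  ac <- autocorrelation_time(a, binwidth = 5)
  expect_equal(ac$tau_corr_ms, -5 / log(0.9), tolerance = 0.12)
  expect_equal(ac$rho$rho[1], 1)  # normalization at lag 0
})

test_that("non-decaying autocorrelation is flagged, not extrapolated", {
  set.seed(17)
  expect_error(autocorrelation_time(rnorm(2000), binwidth = 5),
               "fit failure")
})

test_that("timescale consistency across a sweep", {
  d <- tibble::tibble(m = seq(0.5, 0.95, length.out = 8),
                      tau_corr_ms = branching_timescale(
                        seq(0.5, 0.95, length.out = 8), 4.9))
  expect_equal(branching_consistency(d, 4.9)$rho, 1, tolerance = 1e-9)
  # anti-ordered pairs anticorrelate (the mapping m -> tau is convex, so the
  # coefficient is negative but not -1)
  d2 <- d
  d2$tau_corr_ms <- rev(d2$tau_corr_ms)
  expect_lt(branching_consistency(d2, 4.9)$rho, 0)
  expect_error(branching_consistency(d[1:3, ], 4.9), ">= 5")
})

test_that("van Rossum distance: identity, single-spike quadrature, pair structure", {
  r1 <- new_raster(1L, 100, duration = 300)
  expect_equal(van_rossum_distance(list(r1, r1), sigma = 4.9), 0)

  # one spike vs empty: integrand is 1 on the kernel support
  empty <- new_raster(integer(0), numeric(0), duration = 300)
  d <- van_rossum_distance(list(r1, empty), sigma = 4.9, dt = 0.1)
  # ordered pairs (m,n) and (n,m) both contribute; support = 2*5 sigma
  oracle <- 2 * (2 * 5 * 4.9 + 0.1) / 4.9
  expect_equal(d, oracle, tolerance = 0.01)

  # only pairs involving the shifted trial contribute
  shift <- new_raster(1L, 140, duration = 300)
  d4 <- van_rossum_distance(list(r1, r1, r1, shift), sigma = 4.9)
  d2 <- van_rossum_distance(list(r1, shift), sigma = 4.9)
  expect_equal(d4, 3 * d2, tolerance = 1e-6)
  expect_error(van_rossum_distance(list(r1)), ">= 2")
})

test_that("susceptibility normalization and decoupled response", {
  cfg <- network_config(K_ext = 8, gamma_v = 1)
  topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 18)
  stim <- poisson_stimulus(cfg, 2000, seed = 19)
  pert <- embed_perturbation(stim, 1000, 6, seed = 20)
  # strong external weights, zero recurrence: every pulse spike that lands on
  # an external synapse of some neuron triggers direct spikes only
  w <- matrix(0, cfg$N, cfg$N)
  w[topo$ext == 1] <- 500
  simp <- simulate_network(topo, cfg, pert, w_init = w, seed = 21)
  simb <- simulate_network(topo, cfg, stim, w_init = w, seed = 21)
  chi_p <- susceptibility(simp$spikes, 1000, cfg$K_ext,
                          binwidth = cfg$d_syn, n_units = cfg$N)
  chi_b <- susceptibility(simb$spikes, 1000, cfg$K_ext,
                          binwidth = cfg$d_syn, n_units = cfg$N)
  expect_gt(chi_p, chi_b)
  # doubling K_ext with the same raster halves chi four-fold
  expect_equal(susceptibility(simp$spikes, 1000, 16, cfg$d_syn, cfg$N),
               chi_p / 4)
  expect_error(susceptibility(simp$spikes, 1999.5, 8, cfg$d_syn, cfg$N),
               "out of range")
})
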