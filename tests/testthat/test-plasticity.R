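test_that("STDP kernel: anticausal pair evaluates to the closed form", {
  # post at 10 ms, pre at 11 ms: f = eta * exp(-1/6.8)
  expect_equal(stdp_kernel_sum(pre = 11, post = 10),
               0.071 * exp(-1 / 6.8), tolerance = 1e-12)
  # causal pair (pre before post) contributes nothing
  expect_identical(stdp_kernel_sum(pre = 10, post = 11), 0)
  # empty windows
  expect_identical(stdp_kernel_sum(numeric(0), numeric(0)), 0)
  expect_identical(stdp_kernel_sum(pre = 5, post = numeric(0)), 0)
})

test_that("STDP kernel: nearest-neighbour pairing uses the latest earlier post", {
  # two post spikes before one pre: only the later post (9) pairs
  expect_equal(stdp_kernel_sum(pre = 10, post = c(2, 9)),
               0.071 * exp(-1 / 6.8))
  # two pre spikes each pair with their own latest earlier post
  f <- stdp_kernel_sum(pre = c(10, 12), post = c(9, 11))
  expect_equal(f, 0.071 * (exp(-1 / 6.8) + exp(-1 / 6.8)))
  # R wrapper and C++ core agree on random spike sets
  set.seed(1)
  for (r in 1:20) {
    pre <- sort(runif(sample(0:8, 1), 0, 1000))
    post <- sort(runif(sample(0:8, 1), 0, 1000))
    expect_equal(stdp_kernel_sum(pre, post),
                 cpp_stdp_kernel_sum(pre, post, 0.071, 6.8))
  }
})

test_that("weight update: drift fixed point and lower clip", {
  cfg <- network_config()
  # noise forced to its mean: fixed point of the expected drift is
  # <n>/lambda_drift = (3/16) * 512 = 96
  wstar <- cfg$n_mean / cfg$lambda_drift
  expect_equal(wstar, 96)
  expect_equal(weight_update(wstar, f = 0, cfg, noise = cfg$n_mean), wstar)
  # large depression clips at zero
  expect_equal(weight_update(0, f = 1e6, cfg, noise = cfg$n_mean), 0)
})

test_that("drift-only recursion averages to the fixed point", {
  cfg <- network_config()
  set.seed(99)
  w <- 0
  trace <- numeric(20000)
  for (k in seq_along(trace)) {
    w <- weight_update(w, f = 0, cfg)
    trace[k] <- w
  }
  # discard the rise; sampling error of the mean is < 1
  expect_equal(mean(trace[5000:20000]), 96, tolerance = 0.03)
})

test_that("perturbation embedding changes exactly N_pert events", {
  cfg <- network_config()
  stim <- poisson_stimulus(cfg, 2000, seed = 1)
  pert <- embed_perturbation(stim, t_pert = 1000, N_pert = 6, seed = 2)
  expect_equal(nrow(pert) - nrow(stim), 6L)
  expect_equal(sum(pert$time_ms == 1000) - sum(stim$time_ms == 1000), 6L)
  # unchanged before (and apart from) the pulse
  expect_identical(stim$time_ms[stim$time_ms < 1000],
                   pert$time_ms[pert$time_ms < 1000])
  expect_identical(embed_perturbation(stim, 1000, 0), stim)
  expect_error(embed_perturbation(stim, 5000, 6), "inside the run")
})
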