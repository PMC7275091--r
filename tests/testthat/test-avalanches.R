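test_that("avalanche extraction from population activity", {
  av <- extract_avalanches(c(0, 3, 2, 0, 1, 0))
  expect_equal(av$sizes, c(5L, 1L))
  expect_equal(extract_avalanches(rep(0, 10))$n_avalanches, 0L)
  # no empty bins: one avalanche carrying all spikes
  expect_equal(extract_avalanches(c(2, 1, 3))$sizes, 6L)
})

test_that("avalanche sizes conserve the total spike count", {
  set.seed(7)
  pop <- rpois(5000, 0.7)
  expect_equal(sum(extract_avalanches(pop)$sizes), sum(pop))
})

test_that("truncated power-law MLE recovers known parameters", {
  set.seed(8)
  x <- ref_sample_tpl(1e5, alpha = 1.5, s_cut = 100)
  fit <- fit_truncated_powerlaw(x, s_min = 4, s_max = 96)
  expect_equal(fit$alpha_s, 1.5, tolerance = 0.1 / 1.5)
  expect_equal(fit$s_cut, 100, tolerance = 0.3)
  expect_equal(fit$preferred_model, "power-law")
})

test_that("estimator bias shrinks with sample size", {
  set.seed(9)
  err <- vapply(c(1e3, 1e5), function(n) {
    x <- ref_sample_tpl(n, alpha = 1.5, s_cut = 150)
    abs(fit_truncated_powerlaw(x, 4, 96)$alpha_s - 1.5)
  }, 0)
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.02)
})

test_that("fit range perturbation moves the exponent only slightly", {
  set.seed(10)
  x <- ref_sample_tpl(5e4, alpha = 1.5, s_cut = 100)
  a4 <- fit_truncated_powerlaw(x, 4, 96)$alpha_s
  a5 <- fit_truncated_powerlaw(x, 5, 96)$alpha_s
  expect_lt(abs(a4 - a5), 0.05)
})

test_that("exponential data prefer the exponential model", {
  set.seed(11)
  x <- rgeom(5e4, prob = 1 / 20) + 1L  # discrete exponential-type sizes
  fit <- fit_truncated_powerlaw(x, 4, 96)
  expect_equal(fit$preferred_model, "exponential")
})

test_that("model decision is calibrated on power-law replicates", {
  set.seed(12)
  wins <- vapply(1:100, function(r) {
    x <- ref_sample_tpl(2000, alpha = 1.5, s_cut = 120)
    fit_truncated_powerlaw(x, 4, 96)$preferred_model == "power-law"
  }, TRUE)
  expect_gt(mean(wins), 0.95)
})

test_that("degenerate and insufficient inputs raise typed errors", {
  expect_error(fit_truncated_powerlaw(rep(10L, 500), 4, 96), "degenerate")
  expect_error(fit_truncated_powerlaw(c(5L, 6L), 4, 96), "insufficient")
})

test_that("finite-size scaling slope on exact inputs", {
  d <- data.frame(N = c(16, 32, 64, 128), s_cut = 3 * c(16, 32, 64, 128)^1.6)
  fss <- finite_size_scaling(d)
  expect_equal(fss$exponent, 1.6, tolerance = 1e-10)
  d2 <- data.frame(N = c(16, 32, 64), s_cut = c(16, 32, 64))
  expect_equal(finite_size_scaling(d2)$exponent, 1, tolerance = 1e-10)
  expect_error(finite_size_scaling(data.frame(N = c(16, 32),
                                              s_cut = c(1, 2))), ">= 3")
  expect_gt(finite_size_scaling(d)$std_error, -1e-12)
})

test_that("package sampler agrees with the independent sampler", {
  set.seed(13)
  a <- sample_truncated_powerlaw(4e4, 1.5, 80)
  b <- ref_sample_tpl(4e4, 1.5, 80)
  expect_equal(mean(a), mean(b), tolerance = 0.05)
  expect_equal(mean(a >= 10), mean(b >= 10), tolerance = 0.05)
})
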