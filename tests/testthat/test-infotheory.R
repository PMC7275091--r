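test_that("entropy and mutual information basics", {
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(mutual_information(diag(2) / 2), 1)        # exact copy
  expect_equal(mutual_information(matrix(0.25, 2, 2)), 0) # independence
})

test_that("empirical joints conserve counts and match iid expectations", {
  set.seed(30)
  x <- rbinom(20000, 1, 0.5)
  y <- rbinom(20000, 1, 0.5)
  jt <- build_joint(x, y, l = 2, min_samples = 100)
  expect_equal(sum(jt), 1)
  expect_equal(attr(jt, "n_samples"), 20000 - 2)
  # every cell ~ 2^-(1+2l) for fair independent coins
  expect_true(all(abs(jt - 2^-5) < 0.005))
  expect_error(build_joint(x[1:20], y[1:20], l = 4), "insufficient")
})

test_that("deterministic alternating target has unit entropy marginal", {
  x <- rep(c(0L, 1L), 3000)
  y <- rbinom(6000, 1, 0.5)
  jt <- build_joint(x, y, l = 2, min_samples = 100)
  expect_equal(shannon_entropy(apply(unclass(jt), 1, sum)), 1,
               tolerance = 1e-3)
})

test_that("lagged MI peaks at the embedding delay of a copy", {
  set.seed(31)
  x <- rbinom(50000, 1, 0.5)
  y <- c(rep(0L, 3), x[1:(50000 - 3)])  # y(t) = x(t - 3)
  curve <- lagged_mi(x, y, lags = 1:6)
  expect_equal(which.max(curve$mi_bits), 3L)
  expect_equal(max(curve$mi_bits), 1, tolerance = 1e-3)
  expect_lt(curve$mi_bits[1], 0.01)
})

test_that("lagged MI of a Markov chain matches the closed form", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  pi_st <- c(2 / 3, 1 / 3)
  set.seed(32)
  n <- 3e5
  x <- integer(n)
  x[1] <- 0L
  u <- runif(n)
  for (t in 2:n) x[t] <- as.integer(u[t] < P[x[t - 1] + 1, 2])
  curve <- lagged_mi(x, x, lags = 1:5)
  Pk <- diag(2)
  for (tau in 1:5) {
    Pk <- Pk %*% P
    exact <- mutual_information(diag(pi_st) %*% Pk)
    expect_equal(curve$mi_bits[tau], exact, tolerance = 0.02 + 0.002)
  }
})

test_that("memory capacity sums and bias correction", {
  expect_equal(memory_capacity(rep(0.3, 50), binwidth = 5), 0)
  expect_equal(memory_capacity(c(1, rep(0, 99)), binwidth = 5), 5)
  # geometric decay closed form
  r <- 0.8; cc <- 0.6; N_tau <- 100
  curve <- cc * r^(0:(N_tau - 1))
  oracle <- 5 * (sum(curve) - N_tau * curve[N_tau])
  expect_equal(memory_capacity(curve, 5), oracle)
})

test_that("AIS and TE on the XOR update process are exact", {
  set.seed(33)
  n <- 2e5
  s <- rbinom(n, 1, 0.5)
  x <- integer(n)
  for (t in 2:n) x[t] <- bitwXor(x[t - 1], s[t - 1])
  jt <- build_joint(x, s, l = 1, min_samples = 100)
  expect_equal(active_information_storage(jt), 0, tolerance = 5e-3)
  expect_equal(transfer_entropy(jt), 1, tolerance = 5e-3)
  # chain rule: AIS + TE = joint MI, exactly, for any empirical joint
  expect_equal(active_information_storage(jt) + transfer_entropy(jt),
               joint_mutual_information(jt), tolerance = 1e-12)
  jr <- rand_joint(c(2, 8, 8), seed = 34)
  expect_equal(active_information_storage(jr) + transfer_entropy(jr),
               joint_mutual_information(jr), tolerance = 1e-12)
})

test_that("target iid of its own past has zero storage", {
  set.seed(35)
  x <- rbinom(50000, 1, 0.5)
  y <- rbinom(50000, 1, 0.5)
  jt <- build_joint(x, y, l = 2, min_samples = 100)
  expect_equal(active_information_storage(jt), 0, tolerance = 5e-3)
})
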