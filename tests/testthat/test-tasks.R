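test_that("parity and sum label identities", {
  s <- c(1, 0, 1, 1, 0, 1, 1, 1)
  z <- sum_labels(s, 3)
  p <- parity_labels(s, 3)
  expect_true(all(is.na(z[1:2])))
  expect_equal(z[3], 2L)          # window [1, 0, 1]
  expect_equal(p[3], 0L)
  expect_equal(z[8], 3L)          # all-ones window
  # parity = sum mod 2 everywhere defined
  expect_equal(p[!is.na(p)], z[!is.na(z)] %% 2L)
  # flipping any single bit flips the parity
  for (k in 1:3) {
    s2 <- s; s2[6 - k + 1] <- 1 - s2[6 - k + 1]
    if (6 - k + 1 <= 6 && 6 - k + 1 >= 4) {
      expect_false(parity_labels(s2, 3)[6] == p[6])
    }
  }
  expect_true(all(parity_labels(rep(0, 10), 4)[4:10] == 0))
  set.seed(50)
  s3 <- rbinom(500, 1, 0.4)
  expect_equal(parity_labels(s3, 5)[-(1:4)],
               sum_labels(s3, 5)[-(1:4)] %% 2L)
})

test_that("NARMA recursion: silent-input fixed point and oracle trace", {
  # constant stimulus -> normalized drive 0 -> quadratic fixed point
  x <- narma_series(rep(1, 3000), n = 10)
  xstar <- (0.7 - sqrt(0.7^2 - 4 * 0.05 * 0.1)) / (2 * 0.05)
  expect_equal(tail(x, 1), xstar, tolerance = 1e-6)
  expect_equal(xstar, 0.1443, tolerance = 1e-3)
  # hand-checkable short trace matches the independent recursion
  set.seed(51)
  s <- rbinom(10, 1, 0.5); s[1] <- 1
  expect_equal(narma_series(s, 2), ref_narma(s, 2), tolerance = 1e-12)
  s2 <- rbinom(200, 1, 0.5); s2[1] <- 1
  expect_equal(narma_series(s2, 5), ref_narma(s2, 5), tolerance = 1e-10)
  # first n values are a stimulus-independent transient
  sA <- c(rep(0, 9), 1); sB <- c(1, rep(0, 8), 1)
  expect_equal(narma_series(sA, 10)[1:10], narma_series(sB, 10)[1:10])
  expect_error(narma_series(rep(0, 10), 2), "all-zero")
})

test_that("readout training: separable data, balance invariance, isolation", {
  set.seed(52)
  n <- 400
  lab <- rbinom(n, 1, 0.3)
  act <- cbind(lab, matrix(rnorm(3 * n), n, 3))  # neuron 1 copies the label
  m <- train_readout(act, lab, "parity")
  expect_equal(predict_readout(m, act), lab)
  # duplicating all class-0 samples leaves the balanced solution unchanged
  idx0 <- which(lab == 0)
  m2 <- train_readout(rbind(act, act[idx0, ]), c(lab, lab[idx0]), "parity")
  expect_equal(m$weights, m2$weights, tolerance = 1e-6)
  # labels independent of activity: corrected information near zero
  set.seed(53)
  act_r <- matrix(rnorm(4 * n), n, 4)
  mr <- train_readout(act_r, lab, "parity")
  sc <- score_classifier(mr, act_r, sample(lab), act_r, lab,
                         n_shuffle = 5, seed = 1)
  expect_lt(abs(sc$I_corrected), 0.05)
})

test_that("classifier scoring: perfect, complement, degenerate", {
  set.seed(54)
  lab <- rbinom(300, 1, 0.5)
  act <- cbind(lab)  # scores equal the label
  m <- train_readout(act, lab, "parity")
  sc <- score_classifier(m, act, lab)
  expect_equal(sc$I_raw, shannon_entropy(table(lab)), tolerance = 1e-9)
  expect_equal(sc$I_norm, 1, tolerance = 1e-9)
  # a label-complement predictor carries the same information
  mi_perm <- mutual_information(table(1 - lab, lab))
  expect_equal(mi_perm, sc$I_raw)
  expect_error(score_classifier(m, act, rep(1, 300)), "single-class")
})

test_that("winner-take-all multiclass readout solves a separable sum task", {
  set.seed(55)
  n <- 600
  lab <- sample(0:3, n, replace = TRUE)
  act <- sapply(0:3, function(cl) as.numeric(lab == cl)) +
    matrix(rnorm(4 * n, sd = 0.05), n, 4)
  m <- train_readout(act, lab, "sum")
  expect_gt(mean(predict_readout(m, act) == lab), 0.99)
})

test_that("NARMA scoring conventions", {
  set.seed(56)
  y <- rnorm(500)
  act <- cbind(y)
  m <- train_readout(act, y, "narma")
  sc <- score_narma(m, act, y)
  expect_lt(sc$nrmse, 1e-6)
  # constant offset: NRMSE = |c| / sd(vote)
  sc2 <- score_narma(m, act, y + 0.7)
  expect_equal(sc2$nrmse, 0.7 / sd(y), tolerance = 1e-6)
  # Gaussian residuals of known variance
  x3 <- y + rnorm(500, sd = 0.5)
  sc3 <- score_narma(m, act, x3)
  expect_equal(sc3$nrmse, 0.5 / sd(y), tolerance = 0.1)
})

test_that("shuffle offset is centred at zero across seeds", {
  set.seed(57)
  n <- 500
  act <- matrix(rnorm(4 * n), n, 4)
  lab <- rbinom(n, 1, 0.5)
  m <- train_readout(act, lab, "parity")
  cors <- vapply(1:8, function(s) {
    te_lab <- sample(lab)
    score_classifier(m, act, te_lab, act, lab, n_shuffle = 4,
                     seed = s)$I_corrected
  }, 0)
  expect_lt(abs(mean(cors)), 0.02)
})
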