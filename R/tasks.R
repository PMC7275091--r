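#' Task label generation: n-bit parity and n-bit sum
#'
#' From the binarized shared stimulus `s(t)` (1 ms bins), the parity label is
#' the XOR chain over the `n` most recent bins and the sum label the number of
#' occupied bins (classes `0..n`). Labels are undefined for `t < n` (too
#' little history) and returned as `NA` there; `parity = sum mod 2` holds at
#' every defined `t`.
#'
#' @param s binary stimulus vector.
#' @param n window length.
#' @return Integer labels with `NA` for the first `n - 1` positions.
#' @export
parity_labels <- function(s, n) {
  z <- sum_labels(s, n)
  z %% 2L
}

#' @rdname parity_labels
#' @export
sum_labels <- function(s, n) {
  if (n < 1) abort("n must be >= 1")
  s <- as.integer(s)
  T_ <- length(s)
  if (T_ < n) abort("series shorter than the window")
  cs <- cumsum(s)
  z <- cs - c(rep(0L, n), head(cs, -n))
  z[seq_len(n - 1)] <- NA_integer_
  as.integer(z)
}

#' NARMA target series
#'
#' The order-`n` nonlinear autoregressive moving-average benchmark driven by
#' the normalized stimulus `s~(t) = (s(t) - min s)/(2 max s)`:
#' `x(t) = a x(t-1) + b x(t-1) (1/n) sum(x(t-1..t-n)) + c s~(t-n) s~(t-1) + d`.
#' The series is initialized with `x(t) = 0` for `t <= 0`; out-of-range terms
#' in the running mean contribute 0 and the stimulus product enters only for
#' `t > n`, so the first `n` values are a stimulus-independent transient.
#'
#' @param s stimulus activity (binned counts; must not be all zero).
#' @param n NARMA order.
#' @param a,b,cc,d recursion coefficients (classic values 0.3, 0.05, 1.5,
#'   0.1).
#' @return The target series `x`, same length as `s`.
#' @export
narma_series <- function(s, n, a = 0.3, b = 0.05, cc = 1.5, d = 0.1) {
  if (max(s) <= 0) abort("all-zero stimulus: normalization undefined")
  st <- (s - min(s)) / (2 * max(s))
  T_ <- length(s)
  x <- numeric(T_)
  run_sum <- 0  # sum of the last n values (zeros before the series starts)
  for (t in seq_len(T_)) {
    xm1 <- if (t > 1) x[t - 1] else 0
    drive <- if (t > n) cc * st[t - n] * st[t - 1] else 0
    x[t] <- a * xm1 + b * xm1 * run_sum / n + drive + d
    run_sum <- run_sum + x[t] - (if (t - n >= 1) x[t - n] else 0)
  }
  x
}

#' Train a linear readout on reservoir activity
#'
#' Least-squares weights on the joint activity of the readout neurons, with
#' no intercept (the classification threshold is hardwired at 1/2). For
#' classification tasks every sample is weighted by the inverse relative
#' frequency of its class, so duplicating samples of one class does not move
#' the solution. The sum task trains one one-vs-all unit per class
#' (one-hot targets); NARMA uses plain unweighted least squares. Rank
#' deficiency is handled by a minimum-norm ridge (1e-8).
#'
#' @param activity `T x N_read` matrix of binned activity (1 ms bins).
#' @param labels per-time labels (binary, multiclass integer, or numeric
#'   target for `"narma"`); `NA` rows are dropped.
#' @param task `"parity"`, `"sum"` or `"narma"`.
#' @return An `nc_readout`: weights (matrix `N_read x n_units`), task,
#'   classes.
#' @export
train_readout <- function(activity, labels, task = c("parity", "sum",
                                                     "narma")) {
  task <- match.arg(task)
  activity <- as.matrix(activity)
  keep <- !is.na(labels)
  X <- activity[keep, , drop = FALSE]
  y <- labels[keep]
  ridge <- 1e-8 * diag(ncol(X))
  solve_wls <- function(target, wts) {
    Xw <- X * wts
    drop(solve(crossprod(Xw, X) + ridge, crossprod(Xw, target)))
  }
  if (task == "narma") {
    W <- matrix(solve_wls(y, rep(1, length(y))), ncol = 1)
    classes <- NULL
  } else {
    classes <- sort(unique(y))
    freq <- table(factor(y, levels = classes)) / length(y)
    wts <- as.numeric(1 / freq[as.character(y)])
    if (task == "parity" || length(classes) <= 2) {
      W <- matrix(solve_wls(as.numeric(y == max(classes)), wts), ncol = 1)
    } else {
      W <- vapply(classes, function(cl) solve_wls(as.numeric(y == cl), wts),
                  numeric(ncol(X)))
    }
  }
  structure(list(weights = W, task = task, classes = classes,
                 n_features = ncol(X)),
            class = "nc_readout")
}

#' @rdname train_readout
#' @param model an `nc_readout`.
#' @export
predict_readout <- function(model, activity) {
  activity <- as.matrix(activity)
  scores <- activity %*% model$weights
  if (model$task == "narma") return(drop(scores))
  if (ncol(scores) == 1) {
    cls <- if (is.null(model$classes)) 0:1 else range(model$classes)
    ifelse(drop(scores) - 0.5 >= 0, cls[2], cls[1])
  } else {
    # winner-take-all; ties to the lowest class index
    model$classes[max.col(scores, ties.method = "first")]
  }
}

#' Score a classification readout
#'
#' Plug-in mutual information (bits) between predicted and true labels on the
#' test segment, offset-corrected by retraining the very same classifier on
#' label-shuffled training data (`n_shuffle` replicates, mean offset
#' subtracted), and normalized by the entropy of the true test labels.
#'
#' @param model an `nc_readout` trained on the training segment.
#' @param test_activity,test_labels test segment (disjoint from training).
#' @param train_activity,train_labels training segment, needed for the
#'   shuffle offset; omit to skip the correction.
#' @param n_shuffle shuffle replicates.
#' @param seed seed for the shuffles.
#' @return An `nc_score`: `I_raw`, `I_shuffle`, `I_corrected`, `I_norm`,
#'   `accuracy`, `n_test`.
#' @export
score_classifier <- function(model, test_activity, test_labels,
                             train_activity = NULL, train_labels = NULL,
                             n_shuffle = 10, seed = 1L) {
  keep <- !is.na(test_labels)
  X <- as.matrix(test_activity)[keep, , drop = FALSE]
  y <- test_labels[keep]
  if (length(unique(y)) < 2)
    abort("single-class test labels: mutual information undefined")
  pred <- predict_readout(model, X)
  mi_of <- function(pr) {
    lev <- sort(unique(c(pr, y)))
    mutual_information(table(factor(pr, levels = lev),
                             factor(y, levels = lev)))
  }
  i_raw <- mi_of(pred)
  i_shuf <- 0
  if (!is.null(train_activity) && n_shuffle > 0) {
    set.seed(seed)
    keep_tr <- !is.na(train_labels)
    Xtr <- as.matrix(train_activity)[keep_tr, , drop = FALSE]
    ytr <- train_labels[keep_tr]
    i_shuf <- mean(vapply(seq_len(n_shuffle), function(r) {
      ms <- train_readout(Xtr, sample(ytr), task = model$task)
      mi_of(predict_readout(ms, X))
    }, 0))
  }
  h <- shannon_entropy(table(y))
  structure(list(I_raw = i_raw, I_shuffle = i_shuf,
                 I_corrected = i_raw - i_shuf,
                 I_norm = (i_raw - i_shuf) / h,
                 accuracy = mean(pred == y), n_test = length(y)),
            class = "nc_score")
}

#' @export
print.nc_score <- function(x, ...) {
  cat("<nc_score> I =", signif(x$I_raw, 4), "bits; offset",
      signif(x$I_shuffle, 4), "; corrected", signif(x$I_corrected, 4),
      "; normalized", signif(x$I_norm, 4),
      "; accuracy", round(x$accuracy, 3), "\n")
  invisible(x)
}

#' Score a NARMA readout
#'
#' `NRMSE = sqrt(mean((x - y)^2)) / sd(y)` where `y` is the readout vote
#' (`formula = "standard"`), and its inverse as the performance measure. The
#' as-stated variant `sqrt(mean(x - y) / sd(y))` is available behind
#' `formula = "as-printed"` for comparison.
#'
#' @param model an `nc_readout` with `task = "narma"`.
#' @param test_activity test activity matrix.
#' @param target the NARMA target on the test segment.
#' @param formula `"standard"` or `"as-printed"`.
#' @return A list: `nrmse`, `inv_nrmse`.
#' @export
score_narma <- function(model, test_activity, target,
                        formula = c("standard", "as-printed")) {
  formula <- match.arg(formula)
  keep <- !is.na(target)
  y <- predict_readout(model, as.matrix(test_activity)[keep, , drop = FALSE])
  x <- target[keep]
  sy <- sd(y)
  if (sy == 0) abort("zero-variance readout vote: NRMSE undefined")
  nrmse <- if (formula == "standard") {
    sqrt(mean((x - y)^2)) / sy
  } else {
    sqrt(mean(x - y) / sy)
  }
  list(nrmse = nrmse, inv_nrmse = 1 / nrmse)
}

#' Drive a frozen reservoir with shared input
#'
#' Runs the frozen-weight network under a single shared Poisson stimulus (all
#' external synapses see identical spike times) and returns the 1 ms-binned
#' stimulus and activity, split into training and test segments. One
#' reservoir run can then be scored on any number of tasks via
#' [evaluate_task()].
#'
#' @param w weight matrix (from [burn_in()]).
#' @param topology the matching `nc_topology`.
#' @param config an [network_config()].
#' @param T_train,T_test segment durations in ms.
#' @param seed seed (stimulus `seed`, simulation `seed + 50`).
#' @return An `nc_reservoir`: `s_bin` (binary stimulus), `a_bin`
#'   (`T x N` activity counts), `train_idx`, `test_idx`, metadata.
#' @export
reservoir_run <- function(w, topology, config, T_train = NULL,
                          T_test = NULL, seed = 1L) {
  if (is.null(T_train)) T_train <- config$T_train
  if (is.null(T_test)) T_test <- config$T_test
  dur <- T_train + T_test
  stim <- poisson_stimulus(config, dur, seed = seed, mode = "shared")
  sim <- simulate_network(topology, config, stim, w_init = w,
                          plasticity = FALSE, seed = seed + 50L)
  # shared stimulus: all channels identical, take channel 1
  s_bin <- bin_spikes(filter(stim, .data$unit == 1L), 1, duration = dur,
                      n_units = 1L)$binary[1, ]
  a_bin <- t(bin_spikes(sim$spikes, 1, duration = dur,
                        n_units = config$N)$counts)
  n_train <- floor(T_train)
  structure(list(s_bin = s_bin, a_bin = a_bin,
                 train_idx = seq_len(n_train),
                 test_idx = (n_train + 1):nrow(a_bin),
                 K_ext = topology$K_ext, N = config$N, seed = seed),
            class = "nc_reservoir")
}

#' Evaluate one task on a reservoir run
#'
#' Computes the labels (or NARMA target) from the reservoir's stimulus,
#' trains the linear readout on the training segment using `N_read` randomly
#' selected neurons, and scores it on the disjoint test segment.
#'
#' @param resv an [reservoir_run()] result.
#' @param task `"parity"`, `"sum"` or `"narma"`.
#' @param n window length / NARMA order.
#' @param N_read number of readout neurons (drawn uniformly without
#'   replacement, seeded by `resv$seed + 1`).
#' @param n_shuffle shuffle replicates for the offset correction.
#' @return A one-row tibble: task, n, K_ext, N_read, seed, scores, and
#'   `performance` (normalized corrected information, or 1/NRMSE for NARMA).
#' @export
evaluate_task <- function(resv, task = "parity", n = 5, N_read = 16,
                          n_shuffle = 5) {
  set.seed(resv$seed + 1L)
  sel <- sample.int(resv$N, N_read)
  a <- resv$a_bin[, sel, drop = FALSE]
  tr <- resv$train_idx
  te <- resv$test_idx
  if (task == "narma") {
    x <- narma_series(resv$s_bin, n)
    model <- train_readout(a[tr, ], x[tr], task = "narma")
    sc <- score_narma(model, a[te, ], x[te])
    tibble(task = task, n = n, K_ext = resv$K_ext, N_read = N_read,
           seed = resv$seed, I_corrected = NA_real_, I_norm = NA_real_,
           nrmse = sc$nrmse, inv_nrmse = sc$inv_nrmse,
           performance = sc$inv_nrmse)
  } else {
    lab <- if (task == "parity") parity_labels(resv$s_bin, n)
           else sum_labels(resv$s_bin, n)
    model <- train_readout(a[tr, ], lab[tr], task = task)
    sc <- score_classifier(model, a[te, ], lab[te], a[tr, ], lab[tr],
                           n_shuffle = n_shuffle, seed = resv$seed + 2L)
    tibble(task = task, n = n, K_ext = resv$K_ext, N_read = N_read,
           seed = resv$seed, I_corrected = sc$I_corrected,
           I_norm = sc$I_norm, nrmse = NA_real_, inv_nrmse = NA_real_,
           performance = sc$I_norm)
  }
}

#' @rdname evaluate_task
#' @param w,topology,config,T_train,T_test,seed passed to [reservoir_run()].
#' @export
run_task <- function(w, topology, config, task = "parity", n = 5,
                     N_read = 16, T_train = NULL, T_test = NULL,
                     seed = 1L, n_shuffle = 5) {
  resv <- reservoir_run(w, topology, config, T_train, T_test, seed)
  evaluate_task(resv, task = task, n = n, N_read = N_read,
                n_shuffle = n_shuffle)
}

#' Task performance across a weight-matrix library
#'
#' Evaluates tasks on frozen converged weights for every `K_ext`, returning
#' the per-cell scores and (as an attribute) the `K_ext` maximizing the
#' median performance of each task.
#'
#' @param library_tbl a tibble as returned by binding [burn_in()] results:
#'   columns `K_ext`, `seed`, `w`, `topology`.
#' @param config an [network_config()].
#' @param tasks tibble of task definitions (`task`, `n`, `N_read`); default
#'   parity/sum at n = 5 and 15 with 16 readout neurons.
#' @param T_train,T_test segment durations (ms).
#' @param n_shuffle shuffle replicates.
#' @return A tibble of scores; `attr(, "optima")` maps each task to its best
#'   `K_ext`.
#' @export
task_sweep <- function(library_tbl, config,
                       tasks = tibble(task = c("sum", "sum", "parity",
                                               "parity"),
                                      n = c(5, 15, 5, 15),
                                      N_read = 16),
                       T_train = 100e3, T_test = 21e3, n_shuffle = 3) {
  rows <- purrr::map(seq_len(nrow(library_tbl)), function(i) {
    cfg <- config
    cfg$K_ext <- library_tbl$K_ext[i]
    resv <- reservoir_run(library_tbl$w[[i]], library_tbl$topology[[i]],
                          cfg, T_train = T_train, T_test = T_test,
                          seed = library_tbl$seed[i] + 700L)
    purrr::map(seq_len(nrow(tasks)), function(k) {
      evaluate_task(resv, task = tasks$task[k], n = tasks$n[k],
                    N_read = tasks$N_read[k], n_shuffle = n_shuffle)
    }) %>% bind_rows()
  }) %>% bind_rows()
  optima <- rows %>%
    group_by(.data$task, .data$n, .data$N_read, .data$K_ext) %>%
    summarise(performance = median(.data$performance), .groups = "drop") %>%
    group_by(.data$task, .data$n, .data$N_read) %>%
    summarise(best_K_ext = .data$K_ext[which.max(.data$performance)],
              .groups = "drop")
  attr(rows, "optima") <- optima
  rows
}
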