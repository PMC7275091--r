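#' Branching-ratio estimate from population activity
#'
#' Fits the first-order autoregressive ansatz
#' `<a(t+1) | a(t)> = m * a(t) + h` by ordinary least squares on all
#' successive bin pairs. `m` is the branching ratio (`m = 1` is critical,
#' `m < 1` subcritical) and `h` absorbs the external drive. The branching
#' timescale is `tau_branch = -binwidth / ln(m)`, reported as `Inf` for
#' `m >= 1` and `NA` for `m <= 0`. The conventional binwidth is the
#' refractory period.
#'
#' @param population per-bin population counts, or an `nc_binned`.
#' @param binwidth binwidth in ms (taken from an `nc_binned` automatically).
#' @return An `nc_branching`: `m`, `h`, `tau_branch_ms`, `binwidth`, `n_bins`.
#' @export
estimate_branching_ratio <- function(population, binwidth = NULL) {
  if (inherits(population, "nc_binned")) {
    if (is.null(binwidth)) binwidth <- population$binwidth
    population <- population$population
  }
  if (is.null(binwidth)) abort("binwidth required")
  a <- as.numeric(population)
  if (length(a) < 2) abort("need >= 2 bins")
  a0 <- a[-length(a)]
  a1 <- a[-1]
  if (var(a0) == 0) abort("constant activity: branching ratio undefined")
  fit <- lm(a1 ~ a0)
  m <- unname(coef(fit)[2])
  h <- unname(coef(fit)[1])
  structure(list(m = m, h = h,
                 tau_branch_ms = branching_timescale(m, binwidth),
                 binwidth = binwidth, n_bins = length(a)),
            class = "nc_branching")
}

#' @rdname estimate_branching_ratio
#' @param m branching ratio.
#' @export
branching_timescale <- function(m, binwidth) {
  ifelse(m >= 1, Inf, ifelse(m <= 0, NA_real_, -binwidth / log(m)))
}

#' @export
print.nc_branching <- function(x, ...) {
  cat("<nc_branching> m =", round(x$m, 4), " h =", round(x$h, 3),
      " tau_branch =", round(x$tau_branch_ms, 2), "ms\n")
  invisible(x)
}

#' @export
glance.nc_branching <- function(x, ...) {
  tibble(m = x$m, h = x$h, tau_branch_ms = x$tau_branch_ms,
         binwidth = x$binwidth, n_bins = x$n_bins)
}

#' Autocorrelation time of the population activity
#'
#' Computes the autocorrelation `rho(t')` of `a(t)` (biased autocovariance
#' normalized by the variance, so `rho(0) = 1`) and fits
#' `c * exp(-t'/tau_corr)` by least squares in log space. The fit window
#' covers lags `1..max_lag` but stops before the first non-positive value
#' and, to keep the log-space fit unbiased, before `rho` drops below
#' `exp(-3)` (three decay constants); a series whose lag-1 autocorrelation is
#' indistinguishable from sampling noise (`rho(1) < 2/sqrt(n)`) is flagged as
#' non-decaying rather than fitted.
#'
#' @param population per-bin population counts or an `nc_binned`.
#' @param binwidth binwidth in ms.
#' @param max_lag largest lag used for the fit (default
#'   `min(200, n_bins/4)`).
#' @return An `nc_autocorr`: `tau_corr_ms`, `rho` (tibble `lag`, `rho`),
#'   `binwidth`, `n_lags_fit`.
#' @export
autocorrelation_time <- function(population, binwidth = NULL,
                                 max_lag = NULL) {
  if (inherits(population, "nc_binned")) {
    if (is.null(binwidth)) binwidth <- population$binwidth
    population <- population$population
  }
  if (is.null(binwidth)) abort("binwidth required")
  a <- as.numeric(population)
  n <- length(a)
  if (n < 8) abort("need >= 8 bins")
  if (var(a) == 0) abort("constant activity: autocorrelation undefined")
  if (is.null(max_lag)) max_lag <- max(2L, min(200L, floor(n / 4)))
  ac <- stats::acf(a, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  rho <- tibble(lag = 0:max_lag, rho = as.numeric(ac))
  if (rho$rho[2] < 2 / sqrt(n))
    abort(paste0("lag-1 autocorrelation ", signif(rho$rho[2], 3),
                 " below the noise floor: non-decaying rho, fit failure"))
  usable <- rho$lag >= 1 & rho$rho > exp(-3)
  first_bad <- which(rho$lag >= 1 & rho$rho <= exp(-3))
  if (length(first_bad)) usable <- usable & rho$lag < rho$lag[first_bad[1]]
  d <- rho[usable, ]
  if (nrow(d) < 2)
    abort("autocorrelation does not decay over usable lags: fit failure")
  fit <- lm(log(rho) ~ lag, data = d)
  slope <- unname(coef(fit)[2])
  if (slope >= 0)
    abort("autocorrelation fit has non-negative slope: non-decaying rho")
  tau <- -binwidth / slope
  if (tau > max_lag * binwidth)
    abort(paste0("fitted tau_corr (", round(tau), " ms) exceeds the ",
                 round(max_lag * binwidth), " ms lag window: ",
                 "timescale not identifiable, fit failure"))
  structure(list(tau_corr_ms = -binwidth / slope, rho = rho,
                 binwidth = binwidth, n_lags_fit = nrow(d)),
            class = "nc_autocorr")
}

#' @export
print.nc_autocorr <- function(x, ...) {
  cat("<nc_autocorr> tau_corr =", round(x$tau_corr_ms, 2), "ms  (",
      x$n_lags_fit, "lags fit, binwidth", x$binwidth, "ms )\n")
  invisible(x)
}

#' @export
glance.nc_autocorr <- function(x, ...) {
  tibble(tau_corr_ms = x$tau_corr_ms, binwidth = x$binwidth,
         n_lags_fit = x$n_lags_fit)
}

#' Consistency of autocorrelation and branching timescales
#'
#' Across a sweep (typically over `K_ext`), the directly fitted `tau_corr`
#' should match the branching-derived `tau_branch = -binwidth/ln(m)`. Returns
#' their Pearson correlation.
#'
#' @param data a data frame with columns `tau_corr_ms` and `m`.
#' @param binwidth the binwidth (ms) used for both estimates.
#' @return A list: `rho` (Pearson correlation), `p_value`, `n`.
#' @export
branching_consistency <- function(data, binwidth) {
  stopifnot(all(c("tau_corr_ms", "m") %in% names(data)))
  d <- data[is.finite(data$tau_corr_ms) & data$m > 0 & data$m < 1, ]
  if (nrow(d) < 5) abort("need >= 5 sweep points")
  tb <- branching_timescale(d$m, binwidth)
  ct <- stats::cor.test(d$tau_corr_ms, tb)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Trial-to-trial van Rossum distance
#'
#' Each neuron's spike train is convolved with a Gaussian kernel of width
#' `sigma` (conventionally the refractory period) on a `dt` grid; the distance
#' sums, over ordered trial pairs and neurons, the integral of the squared
#' difference of the convolved signals normalized by their squared sum
#' (defined as 0 wherever both signals vanish), divided by `sigma`.
#' Identical trials give 0.
#'
#' @param trials list of `nc_raster`s sharing `N` and duration.
#' @param sigma kernel width in ms.
#' @param dt integration resolution in ms.
#' @param n_units number of neurons; defaults to the largest id across
#'   trials.
#' @return The distance (dimensionless, >= 0).
#' @export
van_rossum_distance <- function(trials, sigma = 4.9, dt = 0.1,
                                n_units = NULL) {
  if (length(trials) < 2) abort("need >= 2 trials")
  dur <- unique(vapply(trials, raster_duration, 0))
  if (length(dur) != 1) abort("trials must share the duration")
  if (is.null(n_units))
    n_units <- max(vapply(trials, function(r)
      if (nrow(r)) max(r$unit) else 1L, 0L))
  grid <- seq(0, dur, by = dt)
  half <- ceiling(5 * sigma / dt)
  kern <- exp(-(seq(-half, half) * dt)^2 / (2 * sigma^2))
  conv_one <- function(times) {
    sig <- numeric(length(grid) + 2 * half)
    for (tt in times) {
      k <- round(tt / dt) + half + 1
      sig[(k - half):(k + half)] <- sig[(k - half):(k + half)] + kern
    }
    sig[(half + 1):(half + length(grid))]
  }
  smooth <- lapply(trials, function(r) {
    lapply(seq_len(n_units), function(i) conv_one(r$time_ms[r$unit == i]))
  })
  total <- 0
  np <- length(trials)
  for (m in seq_len(np)) for (n_ in seq_len(np)) {
    if (m == n_) next
    for (i in seq_len(n_units)) {
      fm <- smooth[[m]][[i]]; fn <- smooth[[n_]][[i]]
      den <- (fm + fn)^2
      num <- (fm - fn)^2
      ratio <- ifelse(den > 0, num / den, 0)
      total <- total + sum(ratio) * dt
    }
  }
  total / sigma
}

#' Perturbation susceptibility
#'
#' Change of the population activity in the bin right after an embedded input
#' pulse, normalized by `K_ext^2`:
#' `chi = (a(t_pert + binwidth) - a(t_pert)) / K_ext^2`, with the activity
#' binned at the synaptic delay.
#'
#' @param perturbed an `nc_raster` from the run with the embedded pulse.
#' @param t_pert perturbation time (ms).
#' @param K_ext input degree used for the run.
#' @param binwidth bin width (ms), conventionally the synaptic delay.
#' @param n_units number of neurons.
#' @return `chi` (dimensionless).
#' @export
susceptibility <- function(perturbed, t_pert, K_ext, binwidth = 1.9,
                           n_units = NULL) {
  dur <- raster_duration(perturbed)
  b <- bin_spikes(perturbed, binwidth, n_units = n_units)
  k0 <- floor(t_pert / binwidth) + 1
  if (k0 + 1 > length(b$population) || k0 < 1)
    abort("t_pert bins out of range")
  (b$population[k0 + 1] - b$population[k0]) / K_ext^2
}
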