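#' Extract neuronal avalanches
#'
#' An avalanche is a maximal run of consecutive non-empty time bins of the
#' population activity; its size `s` is the number of spikes in the run.
#' Avalanches are separated by at least one empty bin. The conventional
#' binwidth is the mean inter-event interval of the raster (see
#' [mean_inter_event_interval()]).
#'
#' @param population per-bin population counts, or an `nc_binned`.
#' @param binwidth the binwidth used (ms), stored for provenance; filled
#'   automatically from an `nc_binned`.
#' @return An `nc_avalanches`: list with integer `sizes`, `binwidth`,
#'   `n_avalanches`.
#' @examples
#' extract_avalanches(c(0, 3, 2, 0, 1, 0))$sizes  # 5, 1
#' @export
extract_avalanches <- function(population, binwidth = NA_real_) {
  if (inherits(population, "nc_binned")) {
    binwidth <- population$binwidth
    population <- population$population
  }
  r <- rle(population > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cs <- c(0, cumsum(as.numeric(population)))
  sizes <- cs[ends[keep] + 1] - cs[starts[keep]]
  structure(list(sizes = as.integer(sizes), binwidth = binwidth,
                 n_avalanches = length(sizes)),
            class = "nc_avalanches")
}

#' @export
print.nc_avalanches <- function(x, ...) {
  cat("<nc_avalanches>", x$n_avalanches, "avalanches; size range",
      if (x$n_avalanches) paste(range(x$sizes), collapse = "-") else "-",
      "; binwidth", signif(x$binwidth, 4), "ms\n")
  invisible(x)
}

#' @export
tidy.nc_avalanches <- function(x, ...) tibble(size = x$sizes)

# log-likelihood of the discrete truncated power law on [s_min, s_max]
tpl_loglik <- function(alpha, s_cut, x, s_range) {
  logz <- -alpha * log(s_range) - s_range / s_cut
  m <- max(logz)
  lz <- m + log(sum(exp(logz - m)))
  -alpha * sum(log(x)) - sum(x) / s_cut - length(x) * lz
}

#' Fit a discrete truncated power law to avalanche sizes
#'
#' Maximum-likelihood fit of `P(s) proportional to s^-alpha_s * exp(-s/s_cut)`
#' on the integer fit range `[s_min, s_max]` (conventionally `[4, 3N]` for a
#' network of `N` neurons). Sizes are counts, so the discrete distribution is
#' used, normalized by direct summation over the fit range. The likelihood is
#' maximized by an `alpha`-profile search over a log-spaced `s_cut` grid
#' followed by a Nelder-Mead polish; grid ties are broken toward the larger
#' cutoff. For the model decision a pure (untruncated) discrete power law and
#' a discrete exponential (geometric-type) distribution are each fitted on
#' the same range and compared by the plain log-likelihood difference
#' (`loglik_pl` vs `loglik_exp`); the two-parameter truncated law is kept out
#' of this comparison because it nests the exponential.
#'
#' @param sizes integer avalanche sizes (an `nc_avalanches` is accepted).
#' @param s_min,s_max fit range (inclusive).
#' @param min_n minimum number of sizes inside the range (default 100).
#' @param binwidth optional provenance (ms).
#' @return An `nc_plfit`: `alpha_s`, `s_cut`, `s_min`, `s_max`, `loglik_pl`,
#'   `loglik_exp`, `preferred_model`, `n_fit`, `n_total`, `binwidth`.
#' @export
fit_truncated_powerlaw <- function(sizes, s_min = 4, s_max = 96,
                                   min_n = 100, binwidth = NA_real_) {
  if (inherits(sizes, "nc_avalanches")) {
    if (is.na(binwidth)) binwidth <- sizes$binwidth
    sizes <- sizes$sizes
  }
  x <- sizes[sizes >= s_min & sizes <= s_max]
  if (length(x) < min_n)
    abort(paste0("insufficient data: ", length(x), " sizes in [", s_min,
                 ", ", s_max, "], need >= ", min_n))
  if (length(unique(x)) < 2)
    abort("degenerate fit: all sizes in range are equal")
  s_range <- s_min:s_max

  # the cutoff search is bounded at 50 * s_max: beyond that the exponential
  # factor is flat over the whole fit range and the likelihood no longer
  # identifies s_cut
  scut_max <- 50 * s_max
  scut_grid <- exp(seq(log(s_min), log(scut_max), length.out = 30))
  prof <- lapply(scut_grid, function(sc) {
    o <- optimize(function(a) -tpl_loglik(a, sc, x, s_range),
                  interval = c(1e-3, 8))
    list(alpha = o$minimum, ll = -o$objective)
  })
  ll <- vapply(prof, `[[`, 0, "ll")
  # ties toward the larger cutoff
  best <- max(which(ll >= max(ll) - 1e-9))
  start <- c(prof[[best]]$alpha, log(scut_grid[best]))
  op <- optim(start, function(p) -tpl_loglik(p[1], min(exp(p[2]), scut_max),
                                             x, s_range),
              method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10))
  alpha_s <- op$par[1]
  s_cut <- min(exp(op$par[2]), scut_max)
  loglik_tpl <- -op$value

  # pure discrete power law on the same range (for the model comparison)
  pl_ll <- function(a) {
    lz <- log(sum(s_range^(-a)))
    -a * sum(log(x)) - length(x) * lz
  }
  opl <- optimize(function(a) -pl_ll(a), interval = c(1e-3, 8))
  loglik_pl <- -opl$objective

  # discrete exponential competitor on the same range
  exp_ll <- function(lam) {
    logz <- -s_range / lam
    m <- max(logz)
    lz <- m + log(sum(exp(logz - m)))
    -sum(x) / lam - length(x) * lz
  }
  oe <- optimize(function(l) -exp_ll(l), interval = c(0.1, s_max * 50))
  loglik_exp <- -oe$objective

  structure(list(alpha_s = alpha_s, s_cut = s_cut,
                 s_min = s_min, s_max = s_max,
                 loglik_tpl = loglik_tpl,
                 loglik_pl = loglik_pl, loglik_exp = loglik_exp,
                 alpha_pure = opl$minimum, lambda_exp = oe$minimum,
                 preferred_model = if (loglik_pl >= loglik_exp)
                   "power-law" else "exponential",
                 n_fit = length(x), n_total = length(sizes),
                 binwidth = binwidth, sizes = sizes),
            class = "nc_plfit")
}

#' @export
print.nc_plfit <- function(x, ...) {
  cat("<nc_plfit> alpha_s =", round(x$alpha_s, 3),
      " s_cut =", round(x$s_cut, 1),
      " range [", x$s_min, ",", x$s_max, "] n =", x$n_fit, "\n")
  cat("  preferred:", x$preferred_model,
      " (logLik pl - exp =", round(x$loglik_pl - x$loglik_exp, 2), ")\n")
  invisible(x)
}

#' @export
tidy.nc_plfit <- function(x, ...) {
  tibble(term = c("alpha_s", "s_cut"), estimate = c(x$alpha_s, x$s_cut))
}

#' @export
glance.nc_plfit <- function(x, ...) {
  tibble(alpha_s = x$alpha_s, s_cut = x$s_cut,
         loglik_pl = x$loglik_pl, loglik_exp = x$loglik_exp,
         preferred_model = x$preferred_model,
         n_fit = x$n_fit, n_total = x$n_total, binwidth = x$binwidth)
}

#' End-to-end avalanche analysis of a raster
#'
#' Bins the raster at its mean inter-event interval, extracts avalanches and
#' fits the truncated power law on `[s_min, 3N]`.
#'
#' @param raster an `nc_raster` of network spikes.
#' @param n_units number of neurons `N` (sets `s_max = 3 N`); defaults to the
#'   largest unit id.
#' @param s_min lower end of the fit range.
#' @param min_n minimum sizes in range for the fit.
#' @return An `nc_plfit` (with the avalanche set in `$sizes` and the binwidth
#'   recorded).
#' @export
avalanche_analysis <- function(raster, n_units = NULL, s_min = 4,
                               min_n = 100) {
  if (is.null(n_units)) n_units <- max(raster$unit)
  bw <- mean_inter_event_interval(raster)
  pop <- bin_population(raster, bw)
  av <- extract_avalanches(pop, binwidth = bw)
  fit_truncated_powerlaw(av, s_min = s_min, s_max = 3 * n_units,
                         min_n = min_n, binwidth = bw)
}

#' Finite-size scaling of the avalanche cutoff
#'
#' Least-squares slope of `log(s_cut)` against `log(N)`; at criticality the
#' cutoff grows as a power of the system size.
#'
#' @param data a data frame with columns `N` and `s_cut` (one or more rows per
#'   system size).
#' @return An `nc_fss`: `exponent`, `std_error`, `n_points`, and the `lm` fit.
#' @examples
#' finite_size_scaling(data.frame(N = c(16, 32, 64, 128),
#'                                s_cut = 2 * c(16, 32, 64, 128)^1.6))
#' @export
finite_size_scaling <- function(data) {
  stopifnot(all(c("N", "s_cut") %in% names(data)))
  if (length(unique(data$N)) < 3)
    abort("finite-size scaling needs >= 3 system sizes")
  fit <- lm(log(s_cut) ~ log(N), data = data)
  sm <- suppressWarnings(summary(fit))  # exact inputs trip a perfect-fit note
  structure(list(exponent = unname(coef(fit)[2]),
                 std_error = sm$coefficients[2, 2],
                 n_points = nrow(data), fit = fit),
            class = "nc_fss")
}

#' @export
print.nc_fss <- function(x, ...) {
  cat("<nc_fss> scaling exponent =", round(x$exponent, 3),
      "+/-", round(x$std_error, 3), " (", x$n_points, "points )\n")
  invisible(x)
}

#' @export
glance.nc_fss <- function(x, ...) {
  tibble(exponent = x$exponent, std_error = x$std_error,
         n_points = x$n_points)
}

#' Sample from the discrete truncated power law
#'
#' Inverse-CDF sampling of `P(s) proportional to s^-alpha * exp(-s/s_cut)` on
#' `s = s_min, s_min+1, ...` (support truncated where the tail mass falls
#' below 1e-12). Used to generate synthetic avalanche-size fixtures.
#'
#' @param n sample count.
#' @param alpha exponent.
#' @param s_cut exponential cutoff.
#' @param s_min support minimum.
#' @return Integer samples.
#' @export
sample_truncated_powerlaw <- function(n, alpha, s_cut, s_min = 1) {
  s_hi <- max(ceiling(s_cut * 60), s_min + 1000)
  s <- s_min:s_hi
  logp <- -alpha * log(s) - s / s_cut
  p <- exp(logp - max(logp))
  cdf <- cumsum(p) / sum(p)
  s[findInterval(runif(n), cdf) + 1L]
}
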