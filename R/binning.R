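#' Temporal binning of a spike raster
#'
#' Counts spikes per unit in half-open bins `[t*binwidth, (t+1)*binwidth)`.
#' A spike exactly on a bin edge belongs to the bin it opens. The population
#' activity `a(t)` is the per-bin sum over units, the binary state is
#' `min(1, count)`.
#'
#' @param raster an `nc_raster` (any `kind`).
#' @param binwidth bin width in ms.
#' @param duration duration in ms; defaults to the raster's attribute. The
#'   number of bins is `ceiling(duration / binwidth)`.
#' @param n_units number of units (rows of the count matrix); defaults to the
#'   largest unit id present.
#' @return An `nc_binned`: list with `counts` (`n_units x n_bins`), `binary`,
#'   `population` (length `n_bins`), `binwidth`, `duration`.
#' @examples
#' r <- new_raster(c(1, 1, 1), c(0.2, 0.7, 1.1), duration = 2)
#' bin_spikes(r, 1)$counts
#' @export
bin_spikes <- function(raster, binwidth, duration = NULL, n_units = NULL) {
  if (binwidth <= 0) abort("binwidth must be positive")
  if (is.null(duration)) duration <- raster_duration(raster)
  if (is.null(n_units)) n_units <- if (nrow(raster)) max(raster$unit) else 1L
  n_bins <- max(1L, as.integer(ceiling(duration / binwidth - 1e-9)))
  counts <- matrix(0L, n_units, n_bins)
  if (nrow(raster)) {
    # spikes recorded exactly at `duration` are clamped into the last bin
    b <- pmin(floor(raster$time_ms / binwidth), n_bins - 1L) + 1L
    idx <- (b - 1L) * n_units + raster$unit
    counts <- matrix(tabulate(idx, nbins = n_units * n_bins),
                     n_units, n_bins)
  }
  structure(list(counts = counts,
                 binary = pmin(counts, 1L),
                 population = colSums(counts),
                 binwidth = binwidth, duration = duration),
            class = "nc_binned")
}

#' @export
print.nc_binned <- function(x, ...) {
  cat("<nc_binned>", nrow(x$counts), "units x", ncol(x$counts),
      "bins of", x$binwidth, "ms;", sum(x$population), "spikes\n")
  invisible(x)
}

#' @rdname bin_spikes
#' @details `bin_population()` returns only the population activity vector
#'   `a(t)`, without materializing the per-unit count matrix — use it for
#'   fine binwidths or large `N`, where the dense matrix would be large.
#' @export
bin_population <- function(raster, binwidth, duration = NULL) {
  if (binwidth <= 0) abort("binwidth must be positive")
  if (is.null(duration)) duration <- raster_duration(raster)
  n_bins <- max(1L, as.integer(ceiling(duration / binwidth - 1e-9)))
  if (!nrow(raster)) return(integer(n_bins))
  b <- pmin(floor(raster$time_ms / binwidth), n_bins - 1L) + 1L
  tabulate(b, nbins = n_bins)
}

#' Mean inter-event interval
#'
#' Mean of the successive differences of the merged, sorted spike times across
#' all units. This is the canonical avalanche binwidth.
#'
#' @param raster an `nc_raster` with at least two events.
#' @return The mean inter-event interval in ms.
#' @export
mean_inter_event_interval <- function(raster) {
  t <- sort(raster$time_ms)
  if (length(t) < 2)
    abort("mean inter-event interval undefined for < 2 events")
  mean(diff(t))
}

#' Fano factor of the population activity
#'
#' Variance over mean of `a(t)`; by convention computed on activity binned at
#' the refractory period.
#'
#' @param population integer vector of per-bin population counts, or an
#'   `nc_binned`.
#' @return `F = var(a)/mean(a)`.
#' @export
fano_factor <- function(population) {
  if (inherits(population, "nc_binned")) population <- population$population
  m <- mean(population)
  if (m == 0) abort("Fano factor undefined for zero-mean activity")
  var(population) / m
}
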