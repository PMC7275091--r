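#' Spike rasters
#'
#' Spike data are exchanged as tidy tibbles with columns `unit` (integer,
#' 1-based), `time_ms` (double) and `kind` (`"net"` or `"stim"`), sorted by
#' time. `new_raster()` builds and validates one; most users only ever see
#' rasters returned by [simulate_network()] or [poisson_stimulus()].
#'
#' @param unit integer unit ids.
#' @param time_ms spike times in ms.
#' @param kind `"net"` or `"stim"` (recycled).
#' @param duration total duration in ms (stored as the `duration` attribute).
#' @return A tibble of class `nc_raster`.
#' @export
new_raster <- function(unit, time_ms, kind = "net", duration) {
  ord <- order(time_ms, unit)
  out <- tibble(unit = as.integer(unit)[ord], time_ms = time_ms[ord],
                kind = rep_len(kind, length(unit))[ord])
  attr(out, "duration") <- duration
  class(out) <- c("nc_raster", class(out))
  out
}

#' @rdname new_raster
#' @param raster an `nc_raster` (or plain tibble with a `duration`
#'   attribute).
#' @export
raster_duration <- function(raster) {
  d <- attr(raster, "duration")
  if (is.null(d)) max(raster$time_ms) else d
}

#' Poisson stimulus spike trains
#'
#' Generates the external drive: `N` Poisson spike trains of rate `nu`, one
#' per input channel. In `"independent"` mode every channel gets its own
#' train; in `"shared"` mode a single train is copied to all channels (the
#' configuration used for the reservoir-computing tasks, where all external
#' synapses see identical input).
#'
#' @param config an [network_config()].
#' @param duration duration in ms.
#' @param seed stimulus stream seed.
#' @param mode `"independent"` or `"shared"`.
#' @return An `nc_raster` with `kind = "stim"` and channels `1..N`.
#' @export
poisson_stimulus <- function(config, duration, seed = 1L,
                             mode = c("independent", "shared")) {
  mode <- match.arg(mode)
  set.seed(seed)
  N <- config$N
  rate_ms <- config$nu / 1000
  gen_train <- function() {
    if (rate_ms <= 0) return(numeric(0))
    n_exp <- max(10, ceiling(duration * rate_ms * 1.3 + 4 * sqrt(duration * rate_ms)))
    t <- cumsum(rexp(n_exp, rate_ms))
    while (length(t) && t[length(t)] < duration) {
      t <- c(t, t[length(t)] + cumsum(rexp(n_exp, rate_ms)))
    }
    t[t < duration]
  }
  if (mode == "shared") {
    tr <- gen_train()
    unit <- rep(seq_len(N), each = length(tr))
    time <- rep(tr, times = N)
  } else {
    trains <- lapply(seq_len(N), function(i) gen_train())
    unit <- rep(seq_len(N), lengths(trains))
    time <- unlist(trains)
  }
  out <- new_raster(unit, time, "stim", duration)
  attr(out, "mode") <- mode
  out
}

#' Embed a perturbation pulse into a stimulus
#'
#' Adds `N_pert` extra input spikes at time `t_pert`, distributed over
#' `N_pert` distinct input channels chosen at random; the remainder of the
#' stimulus is unchanged. Used for susceptibility measurements, where the
#' perturbed and unperturbed runs share all other seeds.
#'
#' @param stimulus an `nc_raster` of kind `"stim"`.
#' @param t_pert perturbation time (ms), strictly inside the run.
#' @param N_pert number of additional spikes (0 returns the input unchanged).
#' @param n_channels number of input channels to draw from (defaults to the
#'   largest unit id present).
#' @param seed seed for the channel draw.
#' @return An `nc_raster` with the pulse embedded.
#' @export
embed_perturbation <- function(stimulus, t_pert, N_pert,
                               n_channels = NULL, seed = 1L) {
  dur <- raster_duration(stimulus)
  if (t_pert <= 0 || t_pert >= dur)
    abort("t_pert must lie strictly inside the run")
  if (N_pert == 0) return(stimulus)
  if (is.null(n_channels)) n_channels <- max(stimulus$unit)
  if (N_pert > n_channels)
    abort("N_pert exceeds the number of input channels")
  set.seed(seed)
  ch <- sample.int(n_channels, N_pert)
  out <- new_raster(c(stimulus$unit, ch),
                    c(stimulus$time_ms, rep(t_pert, N_pert)),
                    "stim", dur)
  attr(out, "mode") <- attr(stimulus, "mode")
  out
}
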