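#' Simulate the plastic LIF network
#'
#' Clock-driven integration of the current-based leaky integrate-and-fire
#' network on a fixed `dt` grid. Membrane potentials and synaptic currents are
#' advanced with exact exponential decay factors (the dynamics are linear
#' between events); each delivered spike increments the target's synaptic
#' drive by `gamma_v * w[i, j]` (sign from the inhibitory mask) after the
#' synaptic delay; after a threshold crossing the membrane is clamped to
#' `u_reset` for one refractory period. With `plasticity = TRUE` all weights
#' are updated synchronously every `T_update` ms from the spike pairs of the
#' preceding window: anticausal nearest-neighbour STDP depression, weight
#' decay, and positively biased uniform noise, clipped below at zero.
#'
#' Runs are reproducible: the topology and stimulus carry their own seeds and
#' `seed` fixes the plasticity-noise stream.
#'
#' @param topology an [build_topology()] result.
#' @param config an [network_config()].
#' @param stimulus an `nc_raster` of kind `"stim"` (see
#'   [poisson_stimulus()]); may be `NULL` for an undriven network.
#' @param duration duration in ms (defaults to the stimulus duration).
#' @param w_init `N x N` initial weight matrix (defaults to all zero).
#' @param plasticity logical; apply the plasticity rule?
#' @param seed seed for the plasticity noise stream.
#' @param snapshot_every if positive, record the full weight matrix every this
#'   many ms.
#' @param record_u record the membrane trace (memory heavy; short runs only).
#' @param param_seed seed for the per-neuron parameter draw when
#'   `config$param_noise` is set.
#' @return An `nc_sim` list: `spikes` (an `nc_raster`), `w_final`,
#'   `w_trajectory` (tibble `time_ms`, `mean_w` at each plasticity update),
#'   `snapshots`/`snapshot_time_ms`, `rates_hz` (per-neuron mean rate),
#'   optionally `u_trace`, plus the call metadata.
#' @examples
#' cfg <- network_config(K_ext = 8)
#' topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 1)
#' stim <- poisson_stimulus(cfg, 2000, seed = 2)
#' sim <- simulate_network(topo, cfg, stim, plasticity = TRUE, seed = 3)
#' mean(sim$rates_hz)
#' @export
simulate_network <- function(topology, config, stimulus = NULL,
                             duration = NULL, w_init = NULL,
                             plasticity = FALSE, seed = 1L,
                             snapshot_every = 0, record_u = FALSE,
                             param_seed = seed + 101L) {
  stopifnot(inherits(topology, "nc_topology"), inherits(config, "nc_config"))
  N <- topology$N
  if (is.null(duration)) {
    if (is.null(stimulus)) abort("duration required when stimulus is NULL")
    duration <- raster_duration(stimulus)
  }
  if (duration <= 0) abort("duration must be positive")
  dt <- config$dt
  for (nm in c("d_syn", "T_update")) {
    k <- config[[nm]] / dt
    if (abs(k - round(k)) > 1e-6)
      abort(paste0(nm, " = ", config[[nm]], " ms is not a multiple of dt"))
  }
  if (is.null(w_init)) w_init <- matrix(0, N, N)
  stopifnot(all(dim(w_init) == c(N, N)), all(w_init >= 0))
  if (is.null(stimulus)) {
    st <- numeric(0); su <- integer(0)
  } else {
    st <- stimulus$time_ms; su <- stimulus$unit
  }
  pars <- neuron_param_vectors(config, seed = param_seed)
  set.seed(seed)  # plasticity noise stream (consumed inside the C++ core)
  res <- cpp_simulate(N, duration, dt, w_init, topology$ext, topology$inh,
                      st, su,
                      pars$u_thresh, pars$u_leak, pars$u_reset,
                      pars$tau_mem, pars$tau_ref,
                      pars$tau_syn_exc, pars$tau_syn_inh,
                      config$d_syn, config$gamma_v,
                      plasticity,
                      config$lambda_stdp, config$lambda_drift,
                      config$eta_stdp, config$tau_stdp,
                      config$n_amp, config$n_mean, config$T_update,
                      snapshot_every, record_u)
  spikes <- new_raster(res$spike_unit, res$spike_time, "net", duration)
  rates <- tabulate(res$spike_unit, nbins = N) / (duration / 1000)
  out <- list(spikes = spikes,
              w_final = res$w_final,
              w_trajectory = tibble(time_ms = res$traj_time,
                                    mean_w = res$traj_mean_w),
              snapshots = res$snapshots,
              snapshot_time_ms = res$snapshot_time,
              rates_hz = rates,
              duration = duration,
              K_ext = topology$K_ext, N = N,
              plasticity = plasticity, seed = seed)
  if (record_u) out$u_trace <- res$u_trace
  structure(out, class = "nc_sim")
}

#' @export
print.nc_sim <- function(x, ...) {
  cat("<nc_sim> N =", x$N, " K_ext =", x$K_ext,
      " duration =", x$duration / 1000, "s",
      " plasticity =", x$plasticity, "\n")
  cat("  spikes:", nrow(x$spikes),
      " mean rate:", round(mean(x$rates_hz), 2), "Hz\n")
  invisible(x)
}

#' Homeostatic burn-in
#'
#' From zero weights, drives the network with Poisson input while the
#' plasticity rule is active, producing one converged weight matrix per seed.
#' These matrices are the initial conditions for all frozen-weight analyses.
#' The mean rate is reported over the final third of the run, where the
#' homeostatic set point has been reached.
#'
#' @param config an [network_config()]; `K_ext` and the durations are taken
#'   from it.
#' @param duration burn-in duration in ms (default `config$T_burnin`).
#' @param seeds integer vector; one run per seed. Seed `s` is used for the
#'   topology (`s`), stimulus (`s + 1e4`) and plasticity noise (`s + 2e4`)
#'   streams.
#' @param mode topology wiring mode, see [build_topology()].
#' @return A tibble with one row per run: `K_ext`, `seed`, `rate_hz` (mean
#'   over neurons, final third), `w` (list-column of weight matrices),
#'   `topology` (list-column).
#' @export
burn_in <- function(config, duration = NULL, seeds = 1:3,
                    mode = c("hardware-exact", "probabilistic")) {
  mode <- match.arg(mode)
  if (is.null(duration)) duration <- config$T_burnin
  rows <- purrr::map(seeds, function(s) {
    topo <- build_topology(config$N, config$K_ext, config$N_inh,
                           mode = mode, seed = s)
    if (duration <= 0) {
      return(tibble(K_ext = config$K_ext, seed = s, rate_hz = 0,
                    w = list(matrix(0, config$N, config$N)),
                    topology = list(topo)))
    }
    stim <- poisson_stimulus(config, duration, seed = s + 10000L)
    sim <- simulate_network(topo, config, stim, plasticity = TRUE,
                            seed = s + 20000L)
    late <- sim$spikes$time_ms >= duration * 2 / 3
    rate <- sum(late) / config$N / (duration / 3 / 1000)
    tibble(K_ext = config$K_ext, seed = s, rate_hz = rate,
           w = list(sim$w_final), topology = list(topo))
  })
  bind_rows(rows)
}

#' Anticausal nearest-neighbour STDP kernel accumulation
#'
#' Sums `eta_stdp * exp((t_post - t_pre)/tau_stdp)` over nearest-neighbour
#' anticausal pairs: each presynaptic spike inside the window is paired with
#' the latest postsynaptic spike strictly before it. Only pairs with the
#' presynaptic spike after the postsynaptic one contribute (the depressing arm
#' of STDP); causal pairs and empty windows give 0.
#'
#' @param pre,post sorted spike-time vectors (ms) of the pre- and postsynaptic
#'   unit, already restricted to the update window.
#' @param eta_stdp,tau_stdp kernel amplitude and time constant (ms).
#' @return The accumulation `f` (dimensionless).
#' @examples
#' stdp_kernel_sum(pre = 11, post = 10)  # 0.071 * exp(-1/6.8)
#' @export
stdp_kernel_sum <- function(pre, post, eta_stdp = 0.071, tau_stdp = 6.8) {
  if (length(pre) == 0 || length(post) == 0) return(0)
  cpp_stdp_kernel_sum(sort(pre), sort(post), eta_stdp, tau_stdp)
}

#' One plasticity weight update
#'
#' Applies `w' = max(0, w - lambda_stdp * f - lambda_drift * w + n)` with
#' `n ~ unif(-n_amp, n_amp) + n_mean` drawn independently per synapse. With
#' `f = 0` and the noise forced to its mean, the fixed point of the expected
#' drift is `w* = n_mean / lambda_drift`.
#'
#' @param w weight (vector or matrix).
#' @param f STDP accumulation, same shape as `w` (recycled).
#' @param config an [network_config()].
#' @param noise optional fixed noise values (for deterministic checks);
#'   default draws fresh uniform noise.
#' @return Updated weights, clipped below at zero.
#' @export
weight_update <- function(w, f = 0, config = network_config(), noise = NULL) {
  if (is.null(noise))
    noise <- runif(length(w), -config$n_amp, config$n_amp) + config$n_mean
  pmax(0, w - config$lambda_stdp * f - config$lambda_drift * w + noise)
}
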