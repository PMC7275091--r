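#' Network configuration
#'
#' Collects every model parameter into a single validated list: neuron,
#' synapse, plasticity, topology and stimulus parameters plus the experiment
#' durations. Defaults are the reference parameter set of the N = 32
#' current-based LIF network with homeostatic plasticity (drift plus
#' anticausal STDP) under 29 Hz Poisson drive.
#'
#' All times are in milliseconds of biological time unless a name says
#' otherwise. `g_leak` is derived as `C_m / tau_mem` and cannot be set
#' directly.
#'
#' @param N number of neurons.
#' @param K_ext number of input (external) synapses per neuron; the control
#'   parameter for the distance to criticality. `K_ext/N = 1` is a pure
#'   feed-forward network, `K_ext/N = 0` a fully recurrent one.
#' @param N_inh number of inhibitory synapses per neuron.
#' @param u_thresh,u_leak,u_reset membrane threshold, leak and reset
#'   potentials (mV).
#' @param C_m membrane capacitance (nF).
#' @param tau_mem,tau_ref membrane time constant and refractory period (ms).
#' @param tau_syn_exc,tau_syn_inh excitatory/inhibitory synaptic time
#'   constants (ms).
#' @param d_syn synaptic delay (ms), rounded to the integration grid.
#' @param gamma_v weight-to-voltage scaling: the jump (in mV of membrane
#'   drive, i.e. current divided by the leak conductance) that one delivered
#'   spike adds per unit of synaptic weight. See the methods vignette for the
#'   derivation of the default.
#' @param nu external Poisson rate per input channel (Hz).
#' @param lambda_stdp,lambda_drift scaling of the anticausal STDP depression
#'   and of the weight decay (dimensionless).
#' @param eta_stdp,tau_stdp amplitude and time constant (ms) of the STDP
#'   kernel.
#' @param n_amp,n_mean range and bias of the uniform potentiation noise drawn
#'   per synapse per update.
#' @param T_update plasticity update period (ms). Updates are applied
#'   synchronously to all synapses using spike pairs from the preceding
#'   window. The default of 1000 ms (one update per biological second) is the
#'   reading under which the homeostatic balance reproduces the ~20 Hz
#'   working point; see the methods vignette.
#' @param dt integration step (ms).
#' @param param_noise if `TRUE`, per-neuron parameters are drawn from
#'   independent Gaussians with the hardware calibration spreads
#'   (`param_sd`), emulating analog heterogeneity; the default is the
#'   idealized homogeneous model.
#' @param param_sd named list of standard deviations used when
#'   `param_noise = TRUE`.
#' @param T_burnin,T_exp,T_static,T_train,T_test,T_pert experiment durations
#'   (ms): plasticity burn-in, frozen-weight analysis run, per-trial static
#'   run, readout training, readout testing, perturbation run.
#' @param t_pert,N_pert perturbation time (ms) and number of extra input
#'   spikes.
#' @param l embedding dimension for information-theoretic measures.
#' @param N_tau maximal delay (in bins) for lagged mutual information.
#'
#' @return An object of class `nc_config` (a named list).
#' @examples
#' cfg <- network_config(K_ext = 8)
#' cfg$g_leak
#' @export
network_config <- function(N = 32L, K_ext = 8L, N_inh = 6L,
                           u_thresh = 554, u_leak = 384, u_reset = 319,
                           C_m = 2.38, tau_mem = 1.6, tau_ref = 4.9,
                           tau_syn_exc = 3.7, tau_syn_inh = 2.8,
                           d_syn = 1.9, gamma_v = 0.78,
                           nu = 29,
                           lambda_stdp = 11 / 128, lambda_drift = 1 / 512,
                           eta_stdp = 0.071, tau_stdp = 6.8,
                           n_amp = 15 / 16, n_mean = 3 / 16,
                           T_update = 1000, dt = 0.1,
                           param_noise = FALSE,
                           param_sd = list(u_thresh = 21, u_leak = 79,
                                           u_reset = 18, C_m = 0.02,
                                           tau_mem = 1.0, tau_ref = 0.5,
                                           tau_syn_exc = 0.5,
                                           tau_syn_inh = 0.3),
                           T_burnin = 625e3, T_exp = 600e3, T_static = 1e3,
                           T_train = 200e3, T_test = 21e3, T_pert = 2e3,
                           t_pert = 1e3, N_pert = 6L,
                           l = 4L, N_tau = 100L) {
  if (u_reset >= u_thresh) abort("u_reset must be below u_thresh")
  if (tau_mem <= 0 || tau_syn_exc <= 0 || tau_syn_inh <= 0)
    abort("time constants must be positive")
  if (tau_ref < 0 || d_syn < 0) abort("tau_ref and d_syn must be >= 0")
  if (K_ext < 0 || K_ext > N) abort("K_ext must be in [0, N]")
  if (N_inh < 0 || N_inh > N) abort("N_inh must be in [0, N]")
  if (nu < 0) abort("input rate nu must be >= 0")
  if (dt <= 0) abort("dt must be positive")
  cfg <- list(N = as.integer(N), K_ext = as.integer(K_ext),
              N_inh = as.integer(N_inh),
              u_thresh = u_thresh, u_leak = u_leak, u_reset = u_reset,
              C_m = C_m, tau_mem = tau_mem, tau_ref = tau_ref,
              g_leak = C_m / tau_mem,
              tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
              d_syn = d_syn, gamma_v = gamma_v, nu = nu,
              lambda_stdp = lambda_stdp, lambda_drift = lambda_drift,
              eta_stdp = eta_stdp, tau_stdp = tau_stdp,
              n_amp = n_amp, n_mean = n_mean, T_update = T_update,
              dt = dt, param_noise = isTRUE(param_noise), param_sd = param_sd,
              T_burnin = T_burnin, T_exp = T_exp, T_static = T_static,
              T_train = T_train, T_test = T_test, T_pert = T_pert,
              t_pert = t_pert, N_pert = as.integer(N_pert),
              l = as.integer(l), N_tau = as.integer(N_tau))
  structure(cfg, class = "nc_config")
}

#' @export
print.nc_config <- function(x, ...) {
  cat("<nc_config> N =", x$N, " K_ext =", x$K_ext,
      " (K_ext/N =", round(x$K_ext / x$N, 3), ")\n")
  cat("  nu =", x$nu, "Hz  dt =", x$dt, "ms  T_update =", x$T_update, "ms\n")
  cat("  plasticity: lambda_stdp =", signif(x$lambda_stdp, 4),
      " lambda_drift =", signif(x$lambda_drift, 4),
      " <n> =", signif(x$n_mean, 4), "\n")
  invisible(x)
}

#' Read or write a configuration file
#'
#' Configurations are exchanged as a flat YAML or JSON document whose keys
#' mirror the parameter names of [network_config()].
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param config an `nc_config` object.
#' @return `read_config()` returns an `nc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw$g_leak <- NULL
  do.call(network_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nc_config"))
  x <- unclass(config)
  x$g_leak <- NULL
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# per-neuron parameter vectors, optionally with Gaussian hardware-like spread
neuron_param_vectors <- function(config, seed = NULL) {
  N <- config$N
  nm <- c("u_thresh", "u_leak", "u_reset", "tau_mem", "tau_ref",
          "tau_syn_exc", "tau_syn_inh")
  out <- lapply(nm, function(p) rep(config[[p]], N))
  names(out) <- nm
  if (config$param_noise) {
    if (!is.null(seed)) set.seed(seed)
    for (p in nm) {
      s <- config$param_sd[[p]]
      if (!is.null(s) && s > 0) {
        v <- stats::rnorm(N, config[[p]], s)
        # keep the draws physical
        if (p %in% c("tau_mem", "tau_syn_exc", "tau_syn_inh"))
          v <- pmax(v, 0.1)
        if (p == "tau_ref") v <- pmax(v, 0)
        if (p == "u_thresh") v <- pmax(v, out$u_reset + 1)
        out[[p]] <- v
      }
    }
    # threshold must stay above reset neuron-wise
    out$u_thresh <- pmax(out$u_thresh, out$u_reset + 1)
  }
  out
}
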