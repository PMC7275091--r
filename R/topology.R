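#' Build the synaptic topology
#'
#' Every neuron has `N` incoming synapse slots (potential all-to-all
#' connectivity, self-synapses included). Each slot either listens to an
#' external stimulus channel or to a network neuron, never both. In
#' `"hardware-exact"` mode exactly `K_ext` randomly selected slots per neuron
#' are external; in `"probabilistic"` mode (used for finite-size scaling) each
#' slot is external with probability `K_ext/N` and recurrent otherwise, so the
#' external in-degree is `K_ext` only in expectation. `N_inh` slots per neuron
#' are drawn uniformly among all incoming slots to be inhibitory, independent
#' of the external/recurrent designation.
#'
#' @param N,K_ext,N_inh counts; usually taken from a [network_config()].
#' @param mode `"hardware-exact"` or `"probabilistic"`.
#' @param seed integer seed for the topology stream.
#' @return An `nc_topology`: list with `N`, `K_ext`, `N_inh`, `mode`, `seed`
#'   and two `N x N` 0/1 matrices `ext` and `inh`, indexed
#'   `[source, target]`.
#' @examples
#' topo <- build_topology(32, K_ext = 8, seed = 1)
#' colSums(topo$ext)   # exactly 8 external slots per target
#' @export
build_topology <- function(N, K_ext, N_inh = 6L,
                           mode = c("hardware-exact", "probabilistic"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (K_ext < 0 || K_ext > N) abort("K_ext must be in [0, N]")
  if (N_inh < 0 || N_inh > N) abort("N_inh must be in [0, N]")
  set.seed(seed)
  ext <- matrix(0L, N, N)
  inh <- matrix(0L, N, N)
  for (j in seq_len(N)) {
    if (mode == "hardware-exact") {
      if (K_ext > 0) ext[sample.int(N, K_ext), j] <- 1L
    } else {
      ext[, j] <- as.integer(runif(N) < K_ext / N)
    }
    if (N_inh > 0) inh[sample.int(N, N_inh), j] <- 1L
  }
  structure(list(N = as.integer(N), K_ext = as.integer(K_ext),
                 N_inh = as.integer(N_inh), mode = mode,
                 seed = as.integer(seed), ext = ext, inh = inh),
            class = "nc_topology")
}

#' @export
print.nc_topology <- function(x, ...) {
  cat("<nc_topology> N =", x$N, " K_ext =", x$K_ext, " N_inh =", x$N_inh,
      " mode =", x$mode, " seed =", x$seed, "\n")
  cat("  external slots per target:",
      paste(range(colSums(x$ext)), collapse = "-"), "\n")
  invisible(x)
}

#' Rewire the input degree of an existing topology
#'
#' Used by the task-switch experiment: the synapse array is kept (weights stay
#' attached to their `[source, target]` slot) while the set of slots listening
#' to the external input is redrawn for a new `K_ext`. The inhibitory
#' designation is left untouched, as on hardware where inhibition is
#' programmed per synapse driver.
#'
#' @param topology an `nc_topology`.
#' @param K_ext new number of external slots per neuron.
#' @param seed seed for the redraw.
#' @return An `nc_topology` with the new external mask.
#' @export
rewire_input <- function(topology, K_ext, seed = 1L) {
  stopifnot(inherits(topology, "nc_topology"))
  N <- topology$N
  if (K_ext < 0 || K_ext > N) abort("K_ext must be in [0, N]")
  set.seed(seed)
  ext <- matrix(0L, N, N)
  for (j in seq_len(N)) {
    if (topology$mode == "hardware-exact") {
      if (K_ext > 0) ext[sample.int(N, K_ext), j] <- 1L
    } else {
      ext[, j] <- as.integer(runif(N) < K_ext / N)
    }
  }
  out <- topology
  out$K_ext <- as.integer(K_ext)
  out$ext <- ext
  out$seed <- as.integer(seed)
  out
}
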