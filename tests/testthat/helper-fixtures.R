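# Shared fixtures. Heavy simulations used by several acceptance checks are
# computed once per session and cached here.

.nc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .nc_cache)) {
    assign(key, force(expr), envir = .nc_cache)
  }
  get(key, envir = .nc_cache)
}

# a quick converged network for reuse: burn-in at one K_ext
quick_burnin <- function(K_ext = 10, seed = 1, T_burnin = 625e3) {
  cached(paste0("burnin_", K_ext, "_", seed, "_", T_burnin), {
    cfg <- network_config(K_ext = K_ext)
    burn_in(cfg, duration = T_burnin, seeds = seed)
  })
}

# the shared K_ext sweep used by the criticality / consistency / ordering
# acceptance checks (burn-in 625 s, frozen 200 s, 2 seeds)
shared_sweep <- function() {
  cached("sweep", {
    cfg <- network_config()
    run_kext_sweep(cfg, K_grid = c(7, 8, 10, 14, 18, 22, 26, 30),
                   seeds = 1:2, T_burnin = 625e3, T_exp = 200e3,
                   info = TRUE, n_pairs = 4, pid = TRUE,
                   keep_weights = TRUE)
  })
}

# frozen-run validity screen: a cell whose frozen network died (< 1 Hz) or
# runs at the refractory-limited ceiling (> 1/(2 tau_ref) ~ 102 Hz) carries
# no interpretable avalanche/timescale/information structure
valid_cells <- function(sw) {
  dplyr::filter(sw, is.finite(rate_hz), rate_hz >= 1, rate_hz <= 102)
}

rand_joint <- function(d = c(2, 4, 4), seed = 1) {
  set.seed(seed)
  p <- array(rexp(prod(d)), dim = d)
  structure(p / sum(p), class = "nc_joint")
}
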