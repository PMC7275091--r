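# neurocrit

Simulation and analysis of a small plastic spiking recurrent network whose
distance to criticality is controlled by its input connectivity — for
computational neuroscientists and reservoir-computing researchers who want
to study how the collective state of a network (subcritical vs. critical)
shapes its computational properties.

## The model in brief

`N` current-based leaky integrate-and-fire neurons,

    tau_mem du_j/dt = -(u_j - u_leak) + I_j/g_leak ,

potentially all-to-all connected through delta-current synapses with delay.
Of each neuron's `N` incoming synapses, `K_ext` carry external Poisson input
(rate ν = 29 Hz) and the rest carry recurrent spikes; `K_ext/N` sweeps the
network from fully recurrent (0) to feed-forward (1). All weights start at
zero and evolve under a homeostatic rule applied every update period `T`:

    Δw_ij = -λ_stdp f(t_i, t_j) - λ_drift w_ij + n_ij ,
    n_ij ~ unif(-n_amp, n_amp) + ⟨n⟩ ,

where `f` is a nearest-neighbour *anticausal* STDP kernel sum
(`η e^{Δt/τ_stdp}` for pre-after-post pairs): specific depression,
unspecific potentiation. Low `K_ext` lets strong recurrence develop and
drives the network toward a critical state; high `K_ext` keeps it
subcritical.

The analysis stack quantifies that state and its computational
consequences:

- **Avalanches** — binning at the mean inter-event interval, avalanche
  extraction, discrete maximum-likelihood fits of the truncated power law
  `P(s) ∝ s^{-α_s} e^{-s/s_cut}` on `s ∈ [4, 3N]`, power-law vs exponential
  model decision, finite-size scaling of `s_cut`.
- **Branching diagnostics** — branching ratio `m` from the regression of
  `a(t+1)` on `a(t)`, autocorrelation time `τ_corr`, their analytic linkage
  `τ_branch = -δt/ln(m)`, van Rossum trial-to-trial distance, perturbation
  susceptibility `χ`.
- **Information fingerprint** — plug-in entropy, (lagged) mutual
  information, memory capacity, active information storage, transfer
  entropy, and partial information decomposition (unique/shared/synergy)
  via the minimum-synergy convex optimization, solved by entropic mirror
  descent with Sinkhorn marginal projections.
- **Reservoir benchmarks** — n-bit parity, n-bit sum and NARMA targets,
  class-balanced linear readouts with winner-take-all decisions,
  shuffle-corrected mutual-information scores and NRMSE.

Everything is generated in code; there are no external data dependencies.

## Worked example

Burn in a network at `K_ext = 16` (plasticity on, 625 s of biological
time), freeze the converged weights, record 300 s, and analyze:

```r
library(neurocrit)

cfg  <- network_config(K_ext = 16)
topo <- build_topology(cfg$N, cfg$K_ext, cfg$N_inh, seed = 1)
stim <- poisson_stimulus(cfg, 625e3, seed = 10001)
sim  <- simulate_network(topo, cfg, stim, plasticity = TRUE, seed = 20001)
sim
#> <nc_sim> N = 32  K_ext = 16  duration = 625 s  plasticity = TRUE
#>   spikes: 252603  mean rate: 12.63 Hz

frozen <- simulate_network(topo, cfg, poisson_stimulus(cfg, 300e3, 30001),
                           w_init = sim$w_final, seed = 40001)
analyze_run(frozen$spikes, cfg)
#>   rate_hz fano     m tau_branch_ms tau_corr_ms alpha_s s_cut preferred_model
#> 1    51.2 12.3 0.951          98.3         198   0.712  64.9       power-law
#>   n_avalanches max_size binwidth_ms
#> 1        24937      362        0.61
```

The burn-in's whole-run mean (12.6 Hz) is low because the network stays
silent until the potentiation bias has grown the weights into the firing
regime (a few hundred seconds); the converged state fires much faster. The
frozen analysis reads: the network fires at ~51 Hz with strongly
super-Poissonian fluctuations (Fano factor 12), its branching ratio is
0.95 — subcritical but close to the critical point `m = 1` — and the two
independent timescale estimates (`-δt/ln m` ≈ 98 ms from the regression,
198 ms from the autocorrelation fit) agree in order of magnitude. The
avalanche-size distribution (24937 avalanches, binwidth 0.61 ms) is better
fit by a power law than an exponential, with truncated-law exponent 0.71
and cutoff ≈ 65 spikes at this intermediate input degree; the exponent
approaches 1.5 where the cutoff peaks, at `K_ext/N` ≈ 0.55 in this model
(see the sweep below).

Sweep the input degree and plot any metric:

```r
sw <- run_kext_sweep(network_config(), K_grid = c(8, 14, 22, 30),
                     seeds = 1:3, T_burnin = 625e3, T_exp = 200e3)
plot_sweep(sw, m)          # branching ratio vs K_ext/N
aggregate_metrics(sw, K_ext, values = c("m", "alpha_s", "s_cut"))
```

A thin command-line front end is installed with the package
(`system.file("cli", "neurocrit", package = "neurocrit")`) with
`simulate`, `avalanches`, `dynamics` and `info` subcommands operating on
the TSV raster format.

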