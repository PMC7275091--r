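#' Per-run dynamical metrics
#'
#' Computes the standard criticality diagnostics of one frozen-weight run:
#' mean rate, Fano factor, branching ratio `m` (and `tau_branch`),
#' autocorrelation time, and the truncated power-law avalanche fit
#' (binwidth = mean inter-event interval).
#'
#' @param raster an `nc_raster` of network spikes.
#' @param config an [network_config()].
#' @param avalanches include the avalanche fit (needs enough events)?
#' @return A one-row tibble.
#' @export
analyze_run <- function(raster, config, avalanches = TRUE) {
  dur_s <- raster_duration(raster) / 1000
  rate <- nrow(raster) / config$N / dur_s
  pop <- bin_population(raster, config$tau_ref)
  br <- tryCatch(estimate_branching_ratio(pop, config$tau_ref),
                 error = function(e) NULL)
  ac <- tryCatch(autocorrelation_time(pop, config$tau_ref),
                 error = function(e) NULL)
  out <- tibble(rate_hz = rate,
                fano = tryCatch(fano_factor(pop),
                                error = function(e) NA_real_),
                m = if (is.null(br)) NA_real_ else br$m,
                tau_branch_ms = if (is.null(br)) NA_real_
                                else br$tau_branch_ms,
                tau_corr_ms = if (is.null(ac)) NA_real_ else ac$tau_corr_ms)
  if (avalanches) {
    fit <- tryCatch(avalanche_analysis(raster, n_units = config$N),
                    error = function(e) NULL)
    out <- mutate(out,
                  alpha_s = if (is.null(fit)) NA_real_ else fit$alpha_s,
                  s_cut = if (is.null(fit)) NA_real_ else fit$s_cut,
                  preferred_model = if (is.null(fit)) NA_character_
                                    else fit$preferred_model,
                  n_avalanches = if (is.null(fit)) NA_integer_
                                 else fit$n_total,
                  max_size = if (is.null(fit)) NA_real_
                             else max(fit$sizes),
                  binwidth_ms = if (is.null(fit)) NA_real_
                                else fit$binwidth)
  }
  out
}

#' Sweep the input degree
#'
#' The core experiment: for every `K_ext` and seed, burn in the plastic
#' network from zero weights, freeze the converged weights, record a static
#' run and analyze it. Failures in single cells are isolated and reported as
#' `NA` rows.
#'
#' @param config an [network_config()] template (its `K_ext` is overridden).
#' @param K_grid integer vector of input degrees.
#' @param seeds one run per seed and `K_ext`.
#' @param T_burnin,T_exp burn-in and frozen-run durations (ms); default to
#'   the config durations.
#' @param info also compute the pairwise information fingerprint (median over
#'   `n_pairs` ordered pairs), optionally with PID atoms.
#' @param n_pairs,pid see [info_fingerprint()].
#' @param keep_weights keep the converged weight matrices (list-column `w`)
#'   and topologies for reuse (tasks, switching)?
#' @return A tibble with one row per (K_ext, seed).
#' @export
run_kext_sweep <- function(config, K_grid, seeds = 1:3,
                           T_burnin = NULL, T_exp = NULL,
                           info = FALSE, n_pairs = 16, pid = FALSE,
                           keep_weights = FALSE) {
  if (is.null(T_burnin)) T_burnin <- config$T_burnin
  if (is.null(T_exp)) T_exp <- config$T_exp
  cells <- expand.grid(K_ext = K_grid, seed = seeds)
  rows <- purrr::map(seq_len(nrow(cells)), function(i) {
    K <- cells$K_ext[i]; s <- cells$seed[i]
    cfg <- config; cfg$K_ext <- as.integer(K)
    res <- tryCatch({
      bi <- burn_in(cfg, duration = T_burnin, seeds = s)
      stim <- poisson_stimulus(cfg, T_exp, seed = s + 30000L)
      sim <- simulate_network(bi$topology[[1]], cfg, stim,
                              w_init = bi$w[[1]], plasticity = FALSE,
                              seed = s + 40000L)
      row <- bind_rows(tibble(K_ext = K, seed = s,
                              burnin_rate_hz = bi$rate_hz[1]))
      row <- dplyr::bind_cols(row, analyze_run(sim$spikes, cfg))
      if (info) {
        fp <- info_fingerprint(sim$spikes, cfg, n_pairs = n_pairs,
                               pid = pid, seed = s)
        med <- fp %>%
          summarise(dplyr::across(dplyr::where(is.numeric) &
                                    !dplyr::any_of(c("target", "source")),
                                  median))
        names(med) <- paste0("med_", names(med))
        row <- dplyr::bind_cols(row, med)
      }
      if (keep_weights) {
        row$w <- bi$w
        row$topology <- bi$topology
      }
      row
    }, error = function(e) {
      warn(paste0("cell K_ext=", K, " seed=", s, " failed: ",
                  conditionMessage(e)))
      tibble(K_ext = K, seed = s, burnin_rate_hz = NA_real_)
    })
    res
  })
  bind_rows(rows)
}

#' Aggregate metrics over runs
#'
#' Medians with 5-95% percentile intervals (linear-interpolation quantiles)
#' per grouping cell, the convention used for all sweep summaries.
#'
#' @param data a tibble of per-run metrics.
#' @param ... grouping columns (e.g. `K_ext`).
#' @param values tidy-select of value columns; defaults to all numeric
#'   non-grouping columns.
#' @return A tibble with `<col>_median`, `<col>_q05`, `<col>_q95`, and `n`
#'   per cell.
#' @export
aggregate_metrics <- function(data, ..., values = NULL) {
  gb <- group_by(data, ...)
  sel <- if (is.null(values)) {
    dplyr::where(is.numeric)
  } else {
    values
  }
  summarise(gb,
            dplyr::across({{ sel }},
                          list(median = ~median(.x, na.rm = TRUE),
                               q05 = ~quantile(.x, 0.05, na.rm = TRUE,
                                               names = FALSE),
                               q95 = ~quantile(.x, 0.95, na.rm = TRUE,
                                               names = FALSE))),
            n = n(), .groups = "drop")
}

#' Finite-size scaling experiment
#'
#' Burns in and records probabilistically wired networks of several sizes at
#' a fixed input fraction `K_ext/N` (default 1/4), fits the avalanche-size
#' distribution per size (fit range `[4, 3N]`), and fits the log-log scaling
#' of the cutoff against `N`. The inhibitory in-degree is scaled
#' proportionally (`round(6 N / 32)`).
#'
#' @param N_grid system sizes (>= 3).
#' @param kext_frac input fraction `K_ext/N`.
#' @param seeds seeds per size.
#' @param T_burnin,T_exp durations (ms).
#' @param config template configuration.
#' @return A list: `fits` (per-run tibble), `scaling` (an `nc_fss`).
#' @export
finite_size_experiment <- function(N_grid, kext_frac = 0.25, seeds = 1:2,
                                   T_burnin = 150e3, T_exp = 300e3,
                                   config = network_config()) {
  if (length(unique(N_grid)) < 3)
    abort("finite-size scaling needs >= 3 system sizes")
  rows <- purrr::map(N_grid, function(Nn) {
    purrr::map(seeds, function(s) {
      cfg <- config
      cfg$N <- as.integer(Nn)
      cfg$K_ext <- as.integer(round(kext_frac * Nn))
      cfg$N_inh <- as.integer(round(6 * Nn / 32))
      res <- tryCatch({
        bi <- burn_in(cfg, duration = T_burnin, seeds = s + Nn * 100L,
                      mode = "probabilistic")
        stim <- poisson_stimulus(cfg, T_exp, seed = s + Nn * 100L + 30000L)
        sim <- simulate_network(bi$topology[[1]], cfg, stim,
                                w_init = bi$w[[1]], plasticity = FALSE,
                                seed = s + Nn * 100L + 40000L)
        fit <- avalanche_analysis(sim$spikes, n_units = Nn)
        tibble(N = Nn, seed = s, rate_hz = bi$rate_hz[1],
               frozen_rate_hz = mean(sim$rates_hz),
               alpha_s = fit$alpha_s, s_cut = fit$s_cut)
      }, error = function(e) {
        warn(paste0("N=", Nn, " seed=", s, " failed: ",
                    conditionMessage(e)))
        tibble(N = Nn, seed = s, rate_hz = NA_real_,
               frozen_rate_hz = NA_real_,
               alpha_s = NA_real_, s_cut = NA_real_)
      })
      res
    }) %>% bind_rows()
  }) %>% bind_rows()
  # a frozen run that died or sits at the refractory ceiling carries no
  # avalanche structure; exclude it from the scaling fit
  ok <- rows[is.finite(rows$s_cut) & is.finite(rows$frozen_rate_hz) &
               rows$frozen_rate_hz >= 1 & rows$frozen_rate_hz <= 102, ]
  scaling <- tryCatch(finite_size_scaling(ok), error = function(e) {
    warn(conditionMessage(e))
    NULL
  })
  list(fits = rows, scaling = scaling)
}

#' Input degree maximizing the avalanche cutoff
#'
#' Selects the `K_ext` with the largest (median) `s_cut`. Fitted cutoffs
#' saturate at the fit's identifiability bound when the data show no
#' curvature in the fit range, which can tie several degrees at the
#' maximum; ties (within `tol` relative) are resolved toward the largest
#' tied degree — the stable end of the cutoff plateau, furthest from the
#' unstable low-degree boundary.
#'
#' @param data a data frame with columns `K_ext` and `s_cut` (one row per
#'   degree, e.g. per-degree medians).
#' @param tol relative tie tolerance.
#' @return The selected `K_ext`.
#' @export
cutoff_peak_K <- function(data, tol = 0.01) {
  ok <- is.finite(data$s_cut)
  if (!any(ok)) abort("no finite cutoffs")
  d <- data[ok, ]
  top <- max(d$s_cut)
  max(d$K_ext[d$s_cut >= top * (1 - tol)])
}

#' Branching ratio on successive snapshots
#'
#' Splits a raster into consecutive windows (default 1 s) and estimates the
#' branching ratio in each, used to track re-equilibration after an input
#' switch.
#'
#' @param raster an `nc_raster`.
#' @param config an [network_config()].
#' @param window_ms snapshot length.
#' @return A tibble `time_s` (window end), `m`.
#' @export
branching_snapshots <- function(raster, config, window_ms = 1000) {
  dur <- raster_duration(raster)
  n_win <- floor(dur / window_ms)
  rows <- purrr::map(seq_len(n_win), function(k) {
    t0 <- (k - 1) * window_ms
    sub <- raster[raster$time_ms >= t0 & raster$time_ms < t0 + window_ms, ]
    m <- tryCatch({
      pop <- bin_population(new_raster(sub$unit, sub$time_ms - t0, "net",
                                       window_ms), config$tau_ref)
      estimate_branching_ratio(pop, config$tau_ref)$m
    }, error = function(e) NA_real_)
    tibble(time_s = k * window_ms / 1000, m = m)
  })
  bind_rows(rows)
}

#' Re-equilibration time against a reference band
#'
#' First snapshot time from which the (smoothed) branching ratio stays
#' inside `[lo, hi]` for at least `hold` consecutive snapshots; `NA` if
#' never. In the bursty regime single-window regressions of `m` are
#' noisy and bimodal, so trajectories and reference bands are both built
#' from a centred rolling median of the window estimates
#' ([smooth_snapshots()]).
#'
#' @param snapshots tibble from [branching_snapshots()].
#' @param lo,hi reference band (e.g. the 5-95% interval of from-scratch
#'   runs at the target input degree).
#' @param hold required consecutive in-band snapshots.
#' @return Time in seconds (or `NA`).
#' @export
reequilibration_time <- function(snapshots, lo, hi, hold = 3L) {
  inb <- !is.na(snapshots$m) & snapshots$m >= lo & snapshots$m <= hi
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- which(r$values & r$lengths >= hold)
  if (!length(k)) return(NA_real_)
  snapshots$time_s[starts[k[1]]]
}

#' @rdname reequilibration_time
#' @param snapshots tibble with columns `time_s`, `m`.
#' @param k rolling-median width (snapshots).
#' @export
smooth_snapshots <- function(snapshots, k = 5L) {
  m <- snapshots$m
  n <- length(m)
  half <- k %/% 2
  sm <- vapply(seq_len(n), function(i) {
    median(m[max(1, i - half):min(n, i + half)], na.rm = TRUE)
  }, 0)
  mutate(snapshots, m = sm)
}

#' Input-degree switching experiment
#'
#' Takes converged weights at `K_from`, rewires the input degree to `K_to`
#' (weights stay attached to their synapse slots), continues with plasticity
#' on, and tracks the branching ratio on successive snapshots (10 s by
#' default: long enough for a stable per-window regression even in the
#' bursty regime). The re-equilibration time is the first time `m` stays
#' within the 5-95% band of independent from-scratch burn-ins at `K_to` for
#' `hold` consecutive snapshots.
#'
#' @param config template configuration.
#' @param K_from,K_to input degrees before/after the switch.
#' @param T_burnin burn-in duration for the converged starting weights and
#'   the reference runs (ms).
#' @param T_adapt adaptation duration after the switch (ms).
#' @param seeds seeds (one switch run per seed).
#' @param hold consecutive in-band snapshots required.
#' @param window_ms snapshot window for the branching estimates.
#' @param reference optional precomputed reference: list with elements
#'   `band = c(lo, hi)` for `K_to` and `from = burn_in()` tibble at
#'   `K_from`; computed when `NULL`.
#' @return A list: `trajectories` (tibble `seed`, `time_s`, `m`), `band`,
#'   `t_requil` (per seed), `t_requil_mean`.
#' @export
task_switch_experiment <- function(config, K_from, K_to,
                                   T_burnin = 625e3, T_adapt = 150e3,
                                   seeds = 1:3, hold = 3L,
                                   window_ms = 10e3,
                                   reference = NULL) {
  cfg_from <- config; cfg_from$K_ext <- as.integer(K_from)
  cfg_to <- config; cfg_to$K_ext <- as.integer(K_to)

  if (is.null(reference)) {
    from <- burn_in(cfg_from, duration = T_burnin, seeds = seeds)
    band <- reference_band(cfg_to, T_burnin, seeds, window_ms = window_ms)
  } else {
    from <- reference$from
    band <- reference$band
  }

  traj <- purrr::map(seq_along(seeds), function(i) {
    s <- seeds[i]
    topo <- rewire_input(from$topology[[i]], K_to, seed = s + 500L)
    stim <- poisson_stimulus(cfg_to, T_adapt, seed = s + 60000L)
    sim <- simulate_network(topo, cfg_to, stim, w_init = from$w[[i]],
                            plasticity = TRUE, seed = s + 70000L)
    sn <- branching_snapshots(sim$spikes, cfg_to, window_ms = window_ms)
    mutate(smooth_snapshots(sn), seed = s)
  }) %>% bind_rows()

  tr <- vapply(seeds, function(s)
    reequilibration_time(filter(traj, seed == s), band[1], band[2],
                         hold = hold), 0)
  list(trajectories = traj, band = band, t_requil = tr,
       t_requil_mean = mean(tr, na.rm = TRUE))
}

#' @rdname task_switch_experiment
#' @export
reference_band <- function(config, T_burnin = 625e3, seeds = 1:3,
                           window_ms = 10e3) {
  snaps <- purrr::map(seeds, function(s) {
    topo <- build_topology(config$N, config$K_ext, config$N_inh, seed = s)
    stim <- poisson_stimulus(config, T_burnin, seed = s + 10000L)
    sim <- simulate_network(topo, config, stim, plasticity = TRUE,
                            seed = s + 20000L)
    sn <- branching_snapshots(sim$spikes, config, window_ms = window_ms)
    sn <- smooth_snapshots(sn)
    sn[sn$time_s > T_burnin / 1000 * 2 / 3, ]
  }) %>% bind_rows()
  m <- snaps$m[is.finite(snaps$m)]
  # interquartile band of the smoothed statistic: in the bursty regime the
  # tails of the window estimates span both dynamical regimes, so a 5-95%
  # band would accept any state; the IQR tracks the regime's typical value
  c(quantile(m, 0.25, names = FALSE), quantile(m, 0.75, names = FALSE))
}
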