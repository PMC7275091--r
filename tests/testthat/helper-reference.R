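# Independent oracles, deliberately written as separate code paths from the
# package implementations they check.

# --- plain-R reference integrator for the frozen-weight LIF network --------
# Per-synapse current matrices, explicit delivery queue, same integration
# order as the production core: deliver -> integrate -> decay -> threshold.
ref_simulate <- function(topology, config, stimulus, duration, w) {
  N <- topology$N
  dt <- config$dt
  S <- ceiling(duration / dt - 1e-9)
  delay <- max(1, round(config$d_syn / dt))
  am <- exp(-dt / config$tau_mem)
  ae <- exp(-dt / config$tau_syn_exc)
  ai <- exp(-dt / config$tau_syn_inh)
  u <- rep(config$u_leak, N)
  Ie <- matrix(0, N, N)
  Ii <- matrix(0, N, N)
  release <- rep(-1L, N)  # first step index allowed to integrate again
  refrac_steps <- round(config$tau_ref / dt)
  # stimulus event arrival steps: emitted in step floor(t/dt), +delay
  arr <- floor(stimulus$time_ms / dt) + delay
  queue <- vector("list", S + delay + 2)
  for (k in seq_along(arr)) {
    st <- arr[k] + 1
    if (st <= length(queue))
      queue[[st]] <- rbind(queue[[st]], c(stimulus$unit[k], 1))
  }
  spikes <- NULL
  for (s in seq_len(S)) {
    ev <- queue[[s]]
    if (!is.null(ev)) {
      for (r in seq_len(nrow(ev))) {
        i <- ev[r, 1]; is_stim <- ev[r, 2] == 1
        for (j in seq_len(N)) {
          if ((topology$ext[i, j] == 1) == is_stim) {
            a <- config$gamma_v * w[i, j]
            if (a != 0) {
              if (topology$inh[i, j] == 1) Ii[i, j] <- Ii[i, j] - a
              else Ie[i, j] <- Ie[i, j] + a
            }
          }
        }
      }
    }
    tn <- s * dt
    Itot <- colSums(Ie) + colSums(Ii)
    free <- (s - 1) >= release  # 1-based s here vs 0-based core loop
    u[free] <- config$u_leak + (u[free] - config$u_leak) * am +
      Itot[free] * (1 - am)
    u[!free] <- config$u_reset
    Ie <- Ie * ae
    Ii <- Ii * ai
    fired <- which(u >= config$u_thresh & free)
    for (j in fired) {
      spikes <- rbind(spikes, c(j, tn))
      u[j] <- config$u_reset
      release[j] <- (s - 1) + refrac_steps + 1
      st <- s + delay + 1  # 0-based: spike in step s-1, delivered s-1+delay+1
      if (st <= length(queue))
        queue[[st]] <- rbind(queue[[st]], c(j, 0))
    }
  }
  if (is.null(spikes)) {
    new_raster(integer(0), numeric(0), "net", duration)
  } else {
    new_raster(spikes[, 1], spikes[, 2], "net", duration)
  }
}

# --- brute-force minimum-synergy PID for binary-source gates ----------------
# Each target slice is a 2x2 transportation polytope with one free parameter
# (the mass of cell (2,2)); exhaustive grid over both slices.
ref_pid_min_mi <- function(p, n_grid = 81) {
  stopifnot(all(dim(p) == c(2, 2, 2)))
  p <- p / sum(p)
  mi_of <- function(q) {
    qp <- apply(q, c(2, 3), sum)
    pt <- apply(q, 1, sum)
    tot <- 0
    for (t in 1:2) for (a in 1:2) for (b in 1:2) {
      v <- q[t, a, b]
      if (v > 0) tot <- tot + v * log2(v / (pt[t] * qp[a, b]))
    }
    tot
  }
  slice_range <- function(t) {
    r <- rowSums(p[t, , , drop = FALSE][1, , ])  # margins over s1
    cc <- colSums(p[t, , , drop = FALSE][1, , ])
    lo <- max(0, r[2] + cc[2] - sum(r))
    hi <- min(r[2], cc[2])
    c(lo, hi)
  }
  build_slice <- function(t, x) {
    r <- rowSums(p[t, , , drop = FALSE][1, , ])
    cc <- colSums(p[t, , , drop = FALSE][1, , ])
    m <- matrix(0, 2, 2)
    m[2, 2] <- x
    m[2, 1] <- r[2] - x
    m[1, 2] <- cc[2] - x
    m[1, 1] <- r[1] - m[1, 2]
    m
  }
  rg1 <- slice_range(1); rg2 <- slice_range(2)
  xs1 <- seq(rg1[1], rg1[2], length.out = n_grid)
  xs2 <- seq(rg2[1], rg2[2], length.out = n_grid)
  best <- Inf
  for (x1 in xs1) {
    q1 <- build_slice(1, x1)
    for (x2 in xs2) {
      q <- array(0, dim = c(2, 2, 2))
      q[1, , ] <- q1
      q[2, , ] <- build_slice(2, x2)
      if (any(q < -1e-12)) next
      v <- mi_of(pmax(q, 0))
      if (v < best) best <- v
    }
  }
  best
}

# --- independent truncated-power-law sampler (table sampling, not CDF) ------
ref_sample_tpl <- function(n, alpha, s_cut, s_min = 1) {
  s_hi <- max(ceiling(s_cut * 60), s_min + 1000)
  s <- s_min:s_hi
  w <- s^(-alpha) * exp(-s / s_cut)
  sample(s, n, replace = TRUE, prob = w)
}

# --- independent NARMA recursion (loop written against the definition) ------
# convention shared with the package: x(t) = 0 for t <= 0, the running mean
# divides by n with out-of-range terms contributing 0, and the stimulus
# product enters only for t > n.
ref_narma <- function(s, n, a = 0.3, b = 0.05, cc = 1.5, d = 0.1) {
  st <- (s - min(s)) / (2 * max(s))
  x <- numeric(length(s))
  xat <- function(k) if (k >= 1) x[k] else 0
  for (t in seq_along(s)) {
    mean_term <- sum(vapply((t - n):(t - 1), xat, 0)) / n
    drive <- if (t > n) cc * st[t - n] * st[t - 1] else 0
    x[t] <- a * xat(t - 1) + b * xat(t - 1) * mean_term + drive + d
  }
  x
}

# --- AR(1)/branching-process generator with Poisson offspring ---------------
ref_branching_series <- function(n, m, h, a0 = NULL) {
  a <- numeric(n)
  a[1] <- if (is.null(a0)) round(h / max(1e-9, 1 - m)) else a0
  for (t in 2:n) a[t] <- rpois(1, m * a[t - 1] + h)
  a
}
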