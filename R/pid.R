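#' Partial information decomposition (minimum-synergy optimization)
#'
#' Decomposes the joint mutual information `I(target : source1, source2)`
#' into unique, shared (redundant) and synergistic atoms. Following the
#' optimization definition, the solver minimizes `I_Q(target : source1,
#' source2)` over all distributions `Q` that preserve both pairwise marginals
#' `P(target, source_i)`; with the optimum `Q*`:
#' `unique_1 = I_Q*(target : source1 | source2)`,
#' `unique_2 = I_Q*(target : source2 | source1)`,
#' `shared = I(target : source1) - unique_1`, and
#' `synergy = I(target : source1, source2) - I_Q*(target : source1, source2)`.
#' The identities `unique_i + shared = I(target : source_i)` and
#' `sum of atoms = joint MI` hold by construction; atoms are clipped at zero
#' within `clip_tol`.
#'
#' For network use the two sources are the embedded pasts of the target and of
#' a partner process, so `source1` is the target's own past ("self") and
#' `source2` the other process ("other").
#'
#' @param joint an `nc_joint` (array with dims `(target, source1, source2)`),
#'   e.g. from [build_joint()] or [gate_joint()].
#' @param normalize also report atoms normalized by the target entropy.
#' @param step,max_iter,tol mirror-descent step size, iteration cap and
#'   objective-change stopping tolerance (nats).
#' @param clip_tol negative values larger than this in magnitude raise an
#'   error; smaller ones are clipped to 0.
#' @return An `nc_pid`: `I_unq_self`, `I_unq_other`, `I_shd`, `I_syn`,
#'   `I_joint`, `H_target`, normalized variants, and solver diagnostics.
#' @examples
#' broja_pid(gate_joint("xor"))$I_syn   # 1 bit
#' @export
broja_pid <- function(joint, normalize = TRUE, step = 1,
                      max_iter = 20000L, tol = 1e-9, clip_tol = 1e-6) {
  p <- unclass(joint)
  if (length(dim(p)) != 3) abort("joint must have three dimensions")
  p <- p / sum(p)
  d <- dim(p)
  i_joint <- joint_mutual_information(structure(p, class = "nc_joint"))
  i_t1 <- mutual_information(apply(p, c(1, 2), sum))
  i_t2 <- mutual_information(apply(p, c(1, 3), sum))
  h_t <- shannon_entropy(apply(p, 1, sum))

  solve_once <- function(st, mx, tl) {
    sol <- cpp_broja_minimize(as.numeric(p), d[1], d[2], d[3], st, mx, tl)
    q <- array(sol$Q, dim = d)
    q[q < 1e-14] <- 0  # boundary cells the multiplicative iterates approach
    q <- q / sum(q)
    unq1 <- cond_mi_s1_given_s2(q)
    unq2 <- cond_mi_s2_given_s1(q)
    list(sol = sol, q = q,
         atoms = c(I_unq_self = unq1, I_unq_other = unq2,
                   I_shd = i_t1 - unq1, I_syn = i_joint - sol$mi_bits))
  }
  res <- solve_once(step, max_iter, tol)
  if (any(!is.finite(res$atoms)) || any(res$atoms < -clip_tol)) {
    # retry more conservatively before giving up
    res <- solve_once(min(step, 0.3), 2L * max_iter, tol / 100)
  }
  sol <- res$sol
  q <- res$q
  atoms <- res$atoms
  if (any(!is.finite(atoms)) || any(atoms < -clip_tol))
    abort(paste0("solver non-convergence: atoms ",
                 paste(signif(atoms, 4), collapse = ", ")))
  atoms <- pmax(atoms, 0)
  out <- c(as.list(atoms),
           list(I_joint = i_joint, I_self = i_t1, I_other = i_t2,
                H_target = h_t, mi_optimum = sol$mi_bits,
                iterations = sol$iterations, Q = q))
  if (normalize && h_t > 0) {
    out$normalized <- atoms / h_t
  }
  structure(out, class = "nc_pid")
}

# I_Q(T : S1 | S2) on array (t, s1, s2)
cond_mi_s1_given_s2 <- function(q) cond_mi(aperm(q, c(1, 2, 3)))
# I_Q(T : S2 | S1)
cond_mi_s2_given_s1 <- function(q) cond_mi(aperm(q, c(1, 3, 2)))

#' @export
print.nc_pid <- function(x, ...) {
  cat("<nc_pid> joint MI =", round(x$I_joint, 4), "bits\n")
  cat("  unique(self) =", signif(x$I_unq_self, 4),
      " unique(other) =", signif(x$I_unq_other, 4),
      " shared =", signif(x$I_shd, 4),
      " synergy =", signif(x$I_syn, 4), "\n")
  invisible(x)
}

#' @export
tidy.nc_pid <- function(x, ...) {
  tibble(atom = c("unique_self", "unique_other", "shared", "synergy"),
         bits = c(x$I_unq_self, x$I_unq_other, x$I_shd, x$I_syn),
         normalized = if (!is.null(x$normalized)) unname(x$normalized)
                      else NA_real_)
}

#' @export
glance.nc_pid <- function(x, ...) {
  tibble(I_unq_self = x$I_unq_self, I_unq_other = x$I_unq_other,
         I_shd = x$I_shd, I_syn = x$I_syn, I_joint = x$I_joint,
         H_target = x$H_target, iterations = x$iterations)
}

#' Pairwise information fingerprint of a network run
#'
#' Bins a network raster at the refractory period, binarizes it, and computes
#' the plug-in information measures between process pairs: entropy of the
#' target, pairwise mutual information of present states, active information
#' storage, transfer entropy, and (optionally) the partial information
#' decomposition with the target's own past and the partner's past as
#' sources. Pairs can be subsampled for runtime control; the default uses all
#' ordered pairs.
#'
#' @param raster an `nc_raster` of network spikes.
#' @param config an [network_config()] (supplies `tau_ref` and `l`).
#' @param pairs 2-column matrix of (target, source) unit ids, or `NULL` for
#'   all ordered pairs.
#' @param n_pairs if `pairs` is `NULL`, subsample this many ordered pairs
#'   (`Inf` keeps all).
#' @param pid also run the PID solver per pair (the slow part)?
#' @param seed seed for the pair subsample.
#' @return A tibble: `target`, `source`, `H_bits`, `mi_bits`, `ais_bits`,
#'   `te_bits`, and the PID atoms (bits and normalized) when `pid = TRUE`.
#' @export
info_fingerprint <- function(raster, config, pairs = NULL, n_pairs = Inf,
                             pid = FALSE, seed = 1L) {
  N <- config$N
  b <- bin_spikes(raster, config$tau_ref, n_units = N)
  x <- b$binary
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(target = seq_len(N), source = seq_len(N)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (is.finite(n_pairs) && n_pairs < nrow(pairs)) {
      set.seed(seed)
      pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
    }
  }
  rows <- purrr::map(seq_len(nrow(pairs)), function(k) {
    tg <- pairs[k, 1]; sr <- pairs[k, 2]
    tryCatch({
      jt <- build_joint(x[tg, ], x[sr, ], l = config$l, min_samples = 1)
      h <- shannon_entropy(apply(unclass(jt), 1, sum))
      mi <- mutual_information(table(factor(x[tg, ], levels = 0:1),
                                     factor(x[sr, ], levels = 0:1)))
      row <- tibble(target = tg, source = sr, H_bits = h, mi_bits = mi,
                    ais_bits = active_information_storage(jt),
                    te_bits = transfer_entropy(jt))
      if (pid) {
        pd <- broja_pid(jt)
        row <- mutate(row,
                      unq_self_bits = pd$I_unq_self,
                      unq_other_bits = pd$I_unq_other,
                      shd_bits = pd$I_shd, syn_bits = pd$I_syn,
                      joint_mi_bits = pd$I_joint)
      }
      row
    }, error = function(e) {
      warn(paste0("pair (", tg, ", ", sr, ") skipped: ",
                  conditionMessage(e)))
      NULL
    })
  })
  bind_rows(rows)
}
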