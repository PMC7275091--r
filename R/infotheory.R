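#' Shannon entropy and mutual information (plug-in, base 2)
#'
#' `shannon_entropy()` takes a vector/array of probabilities (or counts, which
#' are normalized) and returns the plug-in entropy in bits with the
#' `0 log 0 = 0` convention. `mutual_information()` takes a two-dimensional
#' joint table.
#'
#' @param p probabilities or counts.
#' @return Bits.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) abort("negative probabilities")
  s <- sum(p)
  if (s <= 0) abort("empty distribution")
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

#' @rdname shannon_entropy
#' @param joint a matrix of joint probabilities or counts.
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  joint <- joint / sum(joint)
  shannon_entropy(rowSums(joint)) + shannon_entropy(colSums(joint)) -
    shannon_entropy(joint)
}

# past-state codes: code(t) encodes bins t-1 .. t-l of a binary series, the
# most recent bin in the least significant bit; returned for t = (l+1)..T
embed_codes <- function(x, l) {
  T_ <- length(x)
  if (T_ < l + 1) abort("series too short for embedding")
  code <- integer(T_ - l)
  for (k in seq_len(l)) {
    code <- code + as.integer(x[(l + 1 - k):(T_ - k)]) * 2L^(k - 1L)
  }
  code
}

#' Empirical joint over (present, own past, source past)
#'
#' Builds the plug-in joint distribution of the target's present binary state,
#' its own `l`-bin past state, and a source's `l`-bin past state, from two
#' binarized series (conventionally binned at the refractory period). This is
#' the common input to [active_information_storage()], [transfer_entropy()]
#' and [broja_pid()].
#'
#' @param target,source binary vectors of equal length (0/1).
#' @param l embedding dimension (past-state alphabet `2^l`).
#' @param min_samples floor on usable time points (default `10 * 2^(2l)`).
#' @return An `nc_joint`: array of probabilities with dim
#'   `(2, 2^l, 2^l)` and attributes `n_samples`, `l`.
#' @export
build_joint <- function(target, source, l = 4L,
                        min_samples = 10 * 2^(2 * l)) {
  stopifnot(length(target) == length(source))
  if (!all(target %in% 0:1) || !all(source %in% 0:1))
    abort("series must be binary")
  T_ <- length(target)
  if (T_ - l < min_samples)
    abort(paste0("insufficient data: ", T_ - l, " usable samples, need >= ",
                 min_samples))
  A <- 2L^l
  pres <- as.integer(target[(l + 1):T_])
  pt <- embed_codes(target, l)
  ps <- embed_codes(source, l)
  idx <- 1L + pres + 2L * pt + 2L * A * ps
  cnt <- tabulate(idx, nbins = 2L * A * A)
  p <- array(cnt / sum(cnt), dim = c(2L, A, A))
  structure(p, n_samples = length(pres), l = l, class = "nc_joint")
}

#' Joint distributions of canonical binary gates
#'
#' Returns the `(target, source1, source2)` joint for `target = gate(s1, s2)`
#' with fair, independent binary sources — the standard validation cases for
#' partial information decomposition.
#'
#' @param gate one of `"xor"`, `"and"`, `"copy"` (target copies source 1),
#'   `"unq"` (alias of copy).
#' @return An `nc_joint` array of dim `(2, 2, 2)`.
#' @export
gate_joint <- function(gate = c("xor", "and", "copy", "unq")) {
  gate <- match.arg(gate)
  p <- array(0, dim = c(2, 2, 2))
  for (s1 in 0:1) for (s2 in 0:1) {
    t <- switch(gate, xor = bitwXor(s1, s2), and = s1 * s2,
                copy = s1, unq = s1)
    p[t + 1, s1 + 1, s2 + 1] <- 0.25
  }
  structure(p, n_samples = Inf, l = 1L, class = "nc_joint")
}

# conditional mutual information I(X1 : X2 | X3) in bits from a 3-d array
# with dims (X1, X2, X3)
cond_mi <- function(p) {
  p <- p / sum(p)
  p13 <- apply(p, c(1, 3), sum)
  p23 <- apply(p, c(2, 3), sum)
  p3 <- apply(p, 3, sum)
  tot <- 0
  # probabilities below 1e-15 are numerical dust (e.g. solver iterates
  # decaying toward a boundary); their true contribution is 0
  for (i in seq_len(dim(p)[1])) for (j in seq_len(dim(p)[2]))
    for (k in seq_len(dim(p)[3])) {
      q <- p[i, j, k]
      if (q > 1e-15)
        tot <- tot + q * log2(q * p3[k] / (p13[i, k] * p23[j, k]))
    }
  tot
}

#' Active information storage
#'
#' `AIS = I(present : own past)`, the information a process's present state
#' carries about its own embedded history.
#'
#' @param joint an `nc_joint` from [build_joint()], or a target series (with
#'   `source` supplied, ignored for AIS).
#' @param normalize divide by the entropy of the present state?
#' @return Bits (or a fraction of the target entropy).
#' @export
active_information_storage <- function(joint, normalize = FALSE) {
  p <- unclass(joint)
  m <- apply(p, c(1, 2), sum)  # (present, own past)
  v <- mutual_information(m)
  if (normalize) v <- v / shannon_entropy(apply(p, 1, sum))
  v
}

#' Transfer entropy
#'
#' `TE(source -> target) = I(present : source past | own past)`: the
#' information the source's past provides about the target's present beyond
#' the target's own past. Together with the storage this satisfies the chain
#' rule `AIS + TE = I(present : own past, source past)`.
#'
#' @inheritParams active_information_storage
#' @export
transfer_entropy <- function(joint, normalize = FALSE) {
  p <- unclass(joint)
  # dims (present, own past, source past): condition on own past
  v <- cond_mi(aperm(p, c(1, 3, 2)))
  if (normalize) v <- v / shannon_entropy(apply(p, 1, sum))
  v
}

#' @rdname transfer_entropy
#' @export
joint_mutual_information <- function(joint, normalize = FALSE) {
  p <- unclass(joint)
  d <- dim(p)
  m <- matrix(p, nrow = d[1])  # flatten (own past, source past)
  v <- mutual_information(m)
  if (normalize) v <- v / shannon_entropy(apply(p, 1, sum))
  v
}

#' Lagged mutual information
#'
#' Plug-in mutual information between the present states `x(t)` and
#' `y(t + tau)` for each lag, on binarized series (`l = 1` for both
#' variables). Lags exceeding the series are dropped with a warning.
#'
#' @param x,y binary vectors (source, target).
#' @param lags integer lags (default `1:100`).
#' @return A tibble `lag`, `mi_bits`.
#' @export
lagged_mi <- function(x, y, lags = 1:100) {
  stopifnot(length(x) == length(y))
  T_ <- length(x)
  keep <- lags < T_ - 1
  if (!all(keep)) {
    warn("dropping lags exceeding the series length")
    lags <- lags[keep]
  }
  mi <- vapply(lags, function(tau) {
    xt <- x[1:(T_ - tau)]
    yt <- y[(1 + tau):T_]
    tab <- table(factor(xt, levels = 0:1), factor(yt, levels = 0:1))
    mutual_information(tab)
  }, 0)
  tibble(lag = lags, mi_bits = mi)
}

#' Memory capacity
#'
#' Bias-corrected, lag-summed lagged mutual information:
#' `MC = binwidth * sum_tau (I_tau - I_{N_tau})`, where the value at the
#' largest lag is subtracted as the estimation-bias offset.
#'
#' @param mi_curve tibble from [lagged_mi()] (or a numeric vector of
#'   `I_tau` for `tau = 1..N_tau`).
#' @param binwidth bin width in ms.
#' @param N_tau maximal delay (defaults to the largest lag present).
#' @return Memory capacity in bits * ms.
#' @export
memory_capacity <- function(mi_curve, binwidth, N_tau = NULL) {
  v <- if (is.data.frame(mi_curve)) mi_curve$mi_bits else as.numeric(mi_curve)
  if (is.null(N_tau)) N_tau <- length(v)
  if (length(v) < N_tau) abort("curve shorter than N_tau")
  v <- v[1:N_tau]
  binwidth * sum(v - v[N_tau])
}
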