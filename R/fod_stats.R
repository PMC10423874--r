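# Divergence statistics: Kullback-Leibler divergence in bits, the RD
# relative-distance statistic, the environment-modified target M(K) and the
# grid search for the optimal K.

#' Kullback-Leibler divergence in bits
#'
#' `D(P|Q) = sum_i P_i log2(P_i / Q_i)` with the convention
#' `0 log(0/q) = 0`. An error is raised when some `P_i > 0` has `Q_i = 0`.
#'
#' @param P,Q probability vectors of equal length, each summing to 1.
#' @return Non-negative divergence, bits.
#' @export
kl_divergence <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  if (abs(sum(P) - 1) > 1e-6 || abs(sum(Q) - 1) > 1e-6)
    stop("P and Q must each sum to 1")
  if (any(P < 0) || any(Q < 0)) stop("negative probabilities")
  if (any(P > 0 & Q == 0))
    stop("D(P|Q) undefined: P has mass where Q is zero")
  i <- P > 0
  sum(P[i] * log2(P[i] / Q[i]))
}

# Floor at 1e-12 and renormalize: guards divergences against exact zeros
# produced by floating underflow in Gaussian tails.
floor_norm <- function(p) {
  p <- pmax(p, 1e-12)
  p / sum(p)
}

#' Relative-distance statistic RD
#'
#' `RD = D(O|T) / (D(O|T) + D(O|R))` where R is the uniform reference
#' distribution over the same residues. `RD < 0.5` classifies the unit as
#' having a hydrophobic core (O closer to the Gaussian ideal T than to the
#' flat reference R).
#'
#' @param O,T aligned probability vectors (length >= 2).
#' @return List with `d_ot`, `d_or` (bits), `rd` and the logical flag
#'   `hydrophobic_core`.
#' @export
rd_statistic <- function(O, T) {
  stopifnot(length(O) == length(T), length(O) >= 2)
  O <- floor_norm(O); T <- floor_norm(T)
  R <- rep(1 / length(O), length(O))
  d_ot <- kl_divergence(O, T)
  d_or <- kl_divergence(O, R)
  if (d_ot + d_or == 0)
    stop("RD undefined: O, T and R coincide")
  rd <- d_ot / (d_ot + d_or)
  list(d_ot = d_ot, d_or = d_or, rd = rd, hydrophobic_core = rd < 0.5)
}

#' Environment-modified target distribution M(K)
#'
#' Blends the Gaussian target toward its inverse:
#' `M_i(K) = (T_i + K (Tmax - T_i)) / sum_j (T_j + K (Tmax - T_j))`.
#' `M(0) = T` exactly (pure polar-water field); growing K suppresses the
#' centric core toward the inverted, surface-hydrophobic field typical of
#' membrane-like environments.
#'
#' @param T probability vector.
#' @param K environment parameter, `K >= 0`.
#' @return Probability vector of the same length.
#' @export
m_profile <- function(T, K) {
  if (K < 0) stop("K must be non-negative")
  u <- T + K * (max(T) - T)
  u / sum(u)
}

#' Optimal environment parameter K
#'
#' Dense grid search for `K* = argmin_K D(O | M(K))` over
#' `{0, step, 2 step, ..., k_max}`; ties resolved toward the smallest K.
#' Since `K = 0` is always in the grid, `D(O|M(K*)) <= D(O|T)`.
#'
#' @param O,T aligned probability vectors.
#' @param k_max upper end of the grid (default 10).
#' @param step grid resolution (default 0.01).
#' @return List with `k_opt`, `d_om` (bits) and `k_rounded` (`k_opt` to one
#'   decimal, the precision used in published tables).
#' @export
optimize_k <- function(O, T, k_max = 10, step = 0.01) {
  stopifnot(length(O) == length(T), step > 0, k_max >= 0)
  O <- floor_norm(O); T <- floor_norm(T)
  ks <- seq(0, k_max, by = step)
  tmax <- max(T)
  # columns: unnormalised M(K) for each K
  U <- outer(T, ks, function(t, k) t + k * (tmax - t))
  M <- sweep(U, 2, colSums(U), "/")
  i <- O > 0
  d <- colSums(O[i] * log2(O[i] / M[i, , drop = FALSE]))
  best <- which.min(d)
  list(k_opt = ks[best], d_om = d[best], k_rounded = round(ks[best], 1))
}
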