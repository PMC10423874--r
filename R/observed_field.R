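# Observed hydrophobicity field: distance-damped pairwise hydrophobic
# interactions between residue effective atoms.

#' Distance damping of the hydrophobic interaction
#'
#' The sigmoid polynomial contact function used throughout the fuzzy-oil-
#' drop literature: for `r <= c`,
#' `w = 1 - 1/2 (7(r/c)^2 - 9(r/c)^4 + 5(r/c)^6 - (r/c)^8)`, and 0 beyond
#' the cutoff; continuous at `r = c`. A linear ramp `1 - r/c` is available
#' for sensitivity checks.
#'
#' @param r distance(s), Angstrom; must be non-negative.
#' @param c cutoff, Angstrom (default 9).
#' @param form `"sigmoid"` (default) or `"ramp"`.
#' @return Weight(s) in `[0, 1]`.
#' @export
contact_weight <- function(r, c = 9, form = c("sigmoid", "ramp")) {
  form <- match.arg(form)
  if (any(r < 0)) stop("negative distance")
  stopifnot(c > 0)
  x <- r / c
  w <- if (form == "sigmoid") {
    1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^8)
  } else {
    1 - x
  }
  w[r > c] <- 0
  w
}

#' Observed hydrophobicity profile O
#'
#' Each residue collects hydrophobic interactions from every other residue
#' within the cutoff: `raw_i = sum_{j != i} (H_i + H_j) w(r_ij, c)` over
#' effective-atom distances, then `O = raw / sum(raw)`. The self term is
#' excluded and the pair term is symmetric, so scaling all H by a constant
#' leaves O unchanged.
#'
#' @param points effective-atom coordinate matrix (one row per residue).
#' @param H intrinsic hydrophobicities in `[0, 1]`.
#' @param cutoff interaction cutoff, Angstrom (default 9).
#' @param form contact-function form, see [contact_weight].
#' @return Numeric vector summing to 1.
#' @export
o_profile <- function(points, H, cutoff = 9, form = c("sigmoid", "ramp")) {
  form <- match.arg(form)
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(length(H) == n)
  if (n < 2) stop("observed profile needs at least two residues")
  if (any(is.na(H))) stop("intrinsic hydrophobicity not assigned")
  d <- as.matrix(stats::dist(points))
  w <- contact_weight(d, c = cutoff, form = form)
  diag(w) <- 0
  # raw_i = H_i * sum_j w_ij + sum_j H_j w_ij
  raw <- H * rowSums(w) + as.vector(w %*% H)
  if (sum(raw) <= 0) {
    cause <- if (max(d[upper.tri(d)]) > cutoff && all(w[upper.tri(w)] == 0))
      "no residue pair within the interaction cutoff"
    else "all intrinsic hydrophobicities are zero"
    stop("degenerate observed profile: ", cause)
  }
  unname(raw / sum(raw))
}
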