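# Shared fixture builders: hand-written PDB text, in-code structure units,
# rigid transforms and brute-force oracles kept independent of the package
# internals they check.

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          alt = " ", icode = " ", occ = 1, b = 0,
                          elem = substr(trimws(name), 1, 1)) {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resn, chain, resno, icode, x, y, z, occ, b, elem)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Unit built directly in code: one CA pseudo-atom per residue.
make_unit <- function(coords, aa = "ALA", chain = "A", H = NULL,
                      resno = NULL, ss_bonds = NULL, source = "test") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  aa <- rep_len(aa, n)
  chain <- rep_len(chain, n)
  resno <- if (is.null(resno)) stats::ave(seq_len(n), chain,
                                          FUN = seq_along) else resno
  res <- data.frame(chain = chain, resno = resno, icode = "", aa = aa,
                    x = coords[, 1], y = coords[, 2], z = coords[, 3],
                    H = if (is.null(H)) NA_real_ else rep_len(H, n),
                    effective = "ca", stringsAsFactors = FALSE)
  atoms <- data.frame(res_idx = seq_len(n), elety = "CA",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  structure_unit(res, atoms,
                 if (is.null(ss_bonds)) oildrop:::empty_ss_bonds() else ss_bonds,
                 source = source)
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid-body transform to all coordinates of a unit.
rigid_transform <- function(unit, rot, shift) {
  for (fld in c("residues", "atoms")) {
    m <- as.matrix(unit[[fld]][, c("x", "y", "z")])
    m <- m %*% t(rot)
    m <- sweep(m, 2, shift, "+")
    unit[[fld]][, c("x", "y", "z")] <- m
  }
  unit
}

# Brute-force observed profile: plain double loop, no matrix algebra.
brute_o_profile <- function(coords, H, cutoff = 9) {
  n <- nrow(coords)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r > cutoff) next
      x <- r / cutoff
      w <- 1 - 0.5 * (7 * x^2 - 9 * x^4 + 5 * x^6 - x^8)
      raw[i] <- raw[i] + (H[i] + H[j]) * w
    }
  }
  raw / sum(raw)
}

# Brute-force KL divergence, bits.
brute_kl <- function(P, Q) {
  s <- 0
  for (i in seq_along(P)) if (P[i] > 0) s <- s + P[i] * log2(P[i] / Q[i])
  s
}

# Brute-force interface scan: all cross-chain pairs.
brute_interface <- function(unit, cutoff = 9) {
  res <- unit$residues
  hit <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (res$chain[i] == res$chain[j]) next
      r <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2 +
                  (res$z[i] - res$z[j])^2)
      if (r <= cutoff) { hit[i] <- TRUE; break }
    }
  }
  which(hit)
}
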