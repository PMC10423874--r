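# Seeded generators of synthetic structures with controllable
# micelle-likeness. They emulate the statistical structure the model
# assumes -- a Gaussian residue cloud whose intrinsic hydrophobicity either
# tracks the distance from the centre (ideal micelle), inverts it, or
# ignores it -- so every pipeline stage is testable without downloads.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic single-chain structure unit
#'
#' Residue effective-atom positions are sampled from the 3D Gaussian with
#' the given per-axis sigmas, with a minimum pairwise spacing enforced by
#' rejection. Intrinsic hydrophobicity is set by `mode`:
#' \describe{
#'   \item{`ideal_micelle`}{H decreases with (anisotropic) distance from the
#'     centre: target values spanning the scale range are rank-mapped so the
#'     innermost residue is most hydrophobic.}
#'   \item{`inverted_micelle`}{the reverse: hydrophobic surface, polar core.}
#'   \item{`uniform_h`}{constant mid-range H.}
#'   \item{`mixed`}{the ideal-micelle H values randomly permuted, decoupling
#'     hydrophobicity from geometry.}
#' }
#' Each target H is snapped to the nearest amino acid of the active scale,
#' so the unit remains a valid protein model and survives a PDB round trip
#' with identical hydrophobicities. Residues are written with a single CA
#' pseudo-atom.
#'
#' @param n number of residues (>= 2; default 300).
#' @param seed RNG seed; generation is a pure function of seed and
#'   arguments.
#' @param sigmas per-axis standard deviations, Angstrom (default
#'   `c(14, 11, 9)`).
#' @param mode hydrophobicity pattern (see above).
#' @param n_ss_bonds number of disulfide annotations to add (pairs of
#'   residues converted to CYS).
#' @param min_spacing minimum pairwise distance, Angstrom (default 3.5).
#' @param chain chain identifier (default "A").
#' @param scale hydrophobicity scale (see [hydro_scale]).
#' @return A [structure_unit] with H assigned.
#' @export
synthesize_unit <- function(n = 300, seed = 1, sigmas = c(14, 11, 9),
                            mode = c("ideal_micelle", "inverted_micelle",
                                     "uniform_h", "mixed"),
                            n_ss_bonds = 0, min_spacing = 3.5, chain = "A",
                            scale = "kd") {
  mode <- match.arg(mode)
  stopifnot(n >= 2, all(sigmas > 0))
  sc <- hydro_scale(scale)
  with_seed(seed, {
    pts <- sample_gaussian_points(n, sigmas, min_spacing)
    md <- sqrt(rowSums(sweep(pts, 2, sigmas, "/")^2))
    rk <- rank(md, ties.method = "first")
    targets <- switch(mode,
      ideal_micelle = seq(max(sc), min(sc), length.out = n)[rk],
      inverted_micelle = seq(min(sc), max(sc), length.out = n)[rk],
      uniform_h = rep(stats::median(sc), n),
      mixed = sample(seq(max(sc), min(sc), length.out = n))
    )
    aa <- names(sc)[vapply(targets, function(h) which.min(abs(sc - h)), 1L)]
    ss <- empty_ss_bonds()
    if (n_ss_bonds > 0) {
      stopifnot(2 * n_ss_bonds <= n)
      cand <- order(abs(unname(sc[aa]) - sc[["CYS"]]))[seq_len(2 * n_ss_bonds)]
      cand <- sort(cand)
      aa[cand] <- "CYS"
      for (b in seq_len(n_ss_bonds)) {
        i <- cand[2 * b - 1]; j <- cand[2 * b]
        ss <- rbind(ss, data.frame(chain1 = chain, resno1 = i, icode1 = "",
                                   chain2 = chain, resno2 = j, icode2 = "",
                                   stringsAsFactors = FALSE))
      }
    }
    residues <- data.frame(chain = chain, resno = seq_len(n), icode = "",
                           aa = aa, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                           H = unname(sc[aa]), effective = "ca",
                           stringsAsFactors = FALSE)
    atoms <- data.frame(res_idx = seq_len(n), elety = "CA",
                        x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        stringsAsFactors = FALSE)
    structure_unit(residues, atoms, ss,
                   source = sprintf("synthetic:%s:n%d:seed%d", mode, n, seed))
  })
}

sample_gaussian_points <- function(n, sigmas, min_spacing,
                                   max_attempts = 500 * n) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("rejection sampling failed after ", max_attempts,
           " attempts; use larger sigmas or fewer residues")
    p <- stats::rnorm(3) * sigmas
    if (got > 0) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_spacing^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  pts
}

#' Generate a ground-truth (T, O) profile pair
#'
#' T is a seeded positive normalised vector (gamma-sampled, Dirichlet-like)
#' and `O = M(T, k_true)`, optionally perturbed by multiplicative
#' log-normal noise and renormalised. Used to verify that [optimize_k]
#' recovers a known environment parameter.
#'
#' @param n profile length (>= 2).
#' @param k_true true environment parameter (>= 0).
#' @param seed RNG seed.
#' @param noise standard deviation of the log-normal perturbation
#'   (default 0).
#' @return List with numeric vectors `T` and `O`.
#' @export
gen_profile_pair <- function(n, k_true, seed = 1, noise = 0) {
  stopifnot(n >= 2, k_true >= 0, noise >= 0)
  with_seed(seed, {
    g <- stats::rgamma(n, shape = 2, rate = 1) + 1e-6
    Tv <- g / sum(g)
    Ov <- m_profile(Tv, k_true)
    if (noise > 0) {
      Ov <- Ov * exp(stats::rnorm(n, 0, noise))
      Ov <- Ov / sum(Ov)
    }
    list(T = Tv, O = Ov)
  })
}

#' Generate a synthetic multi-chain complex
#'
#' Generates one chain per config and places consecutive chains with
#' bounding-box centres separated by `gap` along the x axis, so whether an
#' interface exists is controlled by `gap` against the interaction cutoff.
#' Chains are labelled A, B, C, ...
#'
#' @param configs list of per-chain argument lists for [synthesize_unit]
#'   (`n`, `sigmas`, `mode`, ...); at least two.
#' @param gap distance between consecutive chain centres, Angstrom.
#' @param seed base RNG seed (chain k uses `seed + k - 1`).
#' @return A multi-chain [structure_unit].
#' @export
synthesize_complex <- function(configs, gap = 30, seed = 1) {
  stopifnot(length(configs) >= 2)
  chains <- LETTERS[seq_along(configs)]
  parts <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    args <- configs[[k]]
    args$chain <- chains[k]
    args$seed <- if (is.null(args$seed)) seed + k - 1 else args$seed
    u <- do.call(synthesize_unit, args)
    shift <- (k - 1) * gap
    u$residues$x <- u$residues$x + shift
    u$atoms$x <- u$atoms$x + shift
    parts[[k]] <- u
  }
  residues <- do.call(rbind, lapply(parts, `[[`, "residues"))
  rownames(residues) <- NULL
  offs <- cumsum(c(0, vapply(parts, n_residues, 1)[-length(parts)]))
  atoms <- do.call(rbind, lapply(seq_along(parts), function(k) {
    a <- parts[[k]]$atoms
    a$res_idx <- a$res_idx + offs[k]
    a
  }))
  rownames(atoms) <- NULL
  ss <- do.call(rbind, lapply(parts, `[[`, "ss_bonds"))
  structure_unit(residues, atoms, ss,
                 source = sprintf("synthetic_complex:%d chains:seed%d",
                                  length(configs), seed))
}

#' Write a synthetic fixture to disk
#'
#' Writes the unit as a PDB file plus a JSON manifest recording the
#' generator settings, for reproducible test fixtures.
#'
#' @param unit a [structure_unit] produced by a generator.
#' @param path output PDB path; the manifest is written alongside with
#'   extension `.json`.
#' @param manifest named list stored in the manifest (seed, mode, etc.).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(unit, path, manifest = list()) {
  write_structure(unit, path)
  manifest$source <- unit$source
  manifest$n_residues <- n_residues(unit)
  jsonlite::write_json(manifest, sub("\\.pdb$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
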