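# Residue-level structure model: parsing, effective atoms, intrinsic
# hydrophobicity. Each residue is reduced to a single "effective atom"
# (side-chain heavy-atom centroid, CA fallback) carrying an intrinsic
# hydrophobicity H in [0, 1].

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# Common modified residues mapped onto their parent amino acid.
.AA_SUBSTITUTIONS <- c(MSE = "MET", SEC = "CYS", PYL = "LYS",
                       HYP = "PRO", CSO = "CYS", MLY = "LYS",
                       SEP = "SER", TPO = "THR", PTR = "TYR")

.NUCLEIC_RES <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI")

#' Construct a structure unit
#'
#' A structure unit is the object all analyses operate on: an ordered set of
#' residues, each reduced to one effective-atom position and an intrinsic
#' hydrophobicity, plus the heavy atoms they were derived from and any
#' disulfide (SS) bond annotations.
#'
#' @param residues data frame with columns `chain`, `resno`, `icode`, `aa`,
#'   `x`, `y`, `z` (effective-atom coordinates, Angstrom), `H` (intrinsic
#'   hydrophobicity in `[0,1]`, `NA` until assigned) and `effective`
#'   (`"sidechain"` or `"ca"`).
#' @param atoms data frame of heavy atoms with columns `res_idx` (row index
#'   into `residues`), `elety` (PDB atom name), `x`, `y`, `z`.
#' @param ss_bonds data frame of disulfide bonds with columns `chain1`,
#'   `resno1`, `icode1`, `chain2`, `resno2`, `icode2`; may have zero rows.
#' @param source identifier of the structure (e.g. a PDB code or file name).
#' @param skipped character vector describing entities excluded while
#'   parsing (waters, ligands, nucleic-acid chains, extra models).
#'
#' @return An object of class `structure_unit`.
#' @export
structure_unit <- function(residues, atoms, ss_bonds = empty_ss_bonds(),
                           source = "unit", skipped = character()) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1)
  residues$icode[is.na(residues$icode)] <- ""
  key <- residue_keys(residues)
  if (anyDuplicated(key))
    stop("duplicate residue identities: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!all(is.finite(as.matrix(residues[, c("x", "y", "z")]))))
    stop("non-finite effective-atom coordinates")
  if (nrow(ss_bonds) > 0) {
    for (i in seq_len(nrow(ss_bonds))) {
      for (side in 1:2) {
        k <- paste(ss_bonds[[paste0("chain", side)]][i],
                   ss_bonds[[paste0("resno", side)]][i],
                   ss_bonds[[paste0("icode", side)]][i])
        j <- match(k, key)
        if (is.na(j))
          stop("SS-bond endpoint not present in unit: ", k)
        if (residues$aa[j] != "CYS")
          stop("SS-bond endpoint is not a cysteine: ", k)
      }
    }
  }
  structure(list(residues = residues, atoms = atoms, ss_bonds = ss_bonds,
                 source = source, skipped = skipped),
            class = "structure_unit")
}

empty_ss_bonds <- function() {
  data.frame(chain1 = character(), resno1 = integer(), icode1 = character(),
             chain2 = character(), resno2 = integer(), icode2 = character(),
             stringsAsFactors = FALSE)
}

residue_keys <- function(residues) {
  ic <- residues$icode
  ic[is.na(ic)] <- ""
  paste(residues$chain, residues$resno, ic)
}

#' @export
print.structure_unit <- function(x, ...) {
  r <- x$residues
  cat("Structure unit:", x$source, "\n")
  cat(sprintf("  %d residues in %d chain(s): %s\n", nrow(r),
              length(unique(r$chain)),
              paste(unique(r$chain), collapse = ", ")))
  cat(sprintf("  %d SS bond(s); hydrophobicity %s\n", nrow(x$ss_bonds),
              if (all(is.na(r$H))) "not assigned" else "assigned"))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Number of residues in a structure unit
#' @param x a `structure_unit`.
#' @export
n_residues <- function(x) nrow(x$residues)

#' Read a protein structure into a structure unit
#'
#' Parses a PDB file, keeps the first coordinate model only, resolves
#' alternate locations (highest occupancy, ties broken by file order),
#' excludes waters, ligands and nucleic-acid chains, captures SSBOND
#' records, and reduces every standard amino-acid residue to its effective
#' atom.
#'
#' @param path path to the structure file.
#' @param format only `"pdb"` is supported; mmCIF input is not available
#'   and is rejected with an error.
#' @param effective `"sidechain"` (side-chain heavy-atom centroid with CA
#'   fallback, the default) or `"allatom"` (centroid of all heavy atoms).
#' @param nonstandard `"map"` to translate common modified residues (e.g.
#'   MSE to MET) or `"strict"` to fail on any non-standard residue code.
#'
#' @return A [structure_unit] with effective atoms set and `H` unassigned
#'   (see [assign_hydrophobicity]).
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"),
                           effective = c("sidechain", "allatom"),
                           nonstandard = c("map", "strict")) {
  format <- match.arg(format)
  effective <- match.arg(effective)
  nonstandard <- match.arg(nonstandard)
  if (format == "mmcif")
    stop("mmCIF input is not supported; convert to PDB first")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    stop("cannot parse '", path, "' as PDB: ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  skipped <- character()

  n_models <- length(grep("^MODEL", readLines(path, warn = FALSE)))
  if (n_models > 1)
    skipped <- c(skipped, sprintf("%d extra coordinate model(s)", n_models - 1))

  # drop hydrogens/deuterium
  elesy <- at$elesy
  guess <- sub("^[0-9]*", "", at$elety)
  elesy[is.na(elesy) | elesy == ""] <- substr(guess[is.na(elesy) | elesy == ""], 1, 1)
  is_h <- toupper(elesy) %in% c("H", "D")
  at <- at[!is_h, , drop = FALSE]

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "

  resid <- at$resid
  mapped <- resid %in% names(.AA_SUBSTITUTIONS)
  if (nonstandard == "map" && any(mapped))
    resid[mapped] <- .AA_SUBSTITUTIONS[resid[mapped]]

  water <- at$resid %in% c("HOH", "DOD", "WAT")
  nucleic <- at$resid %in% .NUCLEIC_RES
  protein <- resid %in% .STANDARD_AA & !water & !nucleic
  other <- !protein & !water & !nucleic

  if (nonstandard == "strict") {
    aa_like <- at$type == "ATOM" | at$resid %in% names(.AA_SUBSTITUTIONS)
    bad <- unique(at$resid[aa_like & !water & !nucleic &
                             !(at$resid %in% .STANDARD_AA)])
    if (length(bad))
      stop("non-standard residue code(s) under strict policy: ",
           paste(bad, collapse = ", "))
  }

  if (any(water))
    skipped <- c(skipped, sprintf("%d water atom(s)",
                                  sum(water)))
  if (any(nucleic))
    skipped <- c(skipped, sprintf("nucleic-acid chain(s): %s",
                                  paste(unique(at$chain[nucleic]), collapse = ", ")))
  if (any(other))
    skipped <- c(skipped, sprintf("hetero residue(s): %s",
                                  paste(unique(at$resid[other]), collapse = ", ")))

  at$resid <- resid
  at <- at[protein, , drop = FALSE]
  if (nrow(at) == 0)
    stop("no protein residues found in '", path, "'")

  at <- resolve_altloc(at)

  rid <- paste(at$chain, at$resno, at$insert)
  res_first <- !duplicated(rid)
  residues <- data.frame(chain = at$chain[res_first],
                         resno = at$resno[res_first],
                         icode = at$insert[res_first],
                         aa = at$resid[res_first],
                         x = NA_real_, y = NA_real_, z = NA_real_,
                         H = NA_real_, effective = NA_character_,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(res_idx = match(rid, rid[res_first]),
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)

  ss <- parse_ssbond(path)
  # keep only SS bonds whose endpoints survived parsing as CYS
  if (nrow(ss) > 0) {
    key <- residue_keys(residues)
    ok <- logical(nrow(ss))
    for (i in seq_len(nrow(ss))) {
      j1 <- match(paste(ss$chain1[i], ss$resno1[i], ss$icode1[i]), key)
      j2 <- match(paste(ss$chain2[i], ss$resno2[i], ss$icode2[i]), key)
      ok[i] <- !is.na(j1) && !is.na(j2) &&
        residues$aa[j1] == "CYS" && residues$aa[j2] == "CYS"
    }
    if (any(!ok))
      warning(sum(!ok), " SSBOND record(s) with unresolved endpoints dropped")
    ss <- ss[ok, , drop = FALSE]
  }

  residues <- compute_effective(residues, atoms, method = effective)
  structure_unit(residues, atoms, ss, source = basename(path),
                 skipped = skipped)
}

# Alternate locations: keep the highest-occupancy copy of each
# (chain, resno, icode, atom name); ties keep the first encountered.
resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(alt == "")) return(at)
  at$o[is.na(at$o)] <- 1
  aid <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(factor(aid, levels = unique(aid)), -at$o)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
     drop = FALSE]
}

parse_ssbond <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ss <- lines[startsWith(lines, "SSBOND")]
  out <- empty_ss_bonds()
  for (l in ss) {
    l <- formatC(l, width = 40, flag = "-")
    out <- rbind(out, data.frame(
      chain1 = trimws(substr(l, 16, 16)),
      resno1 = as.integer(trimws(substr(l, 18, 21))),
      icode1 = trimws(substr(l, 22, 22)),
      chain2 = trimws(substr(l, 30, 30)),
      resno2 = as.integer(trimws(substr(l, 32, 35))),
      icode2 = trimws(substr(l, 36, 36)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Compute effective-atom positions for every residue
#'
#' The effective atom is the arithmetic mean of the side-chain heavy atoms
#' (all atoms beyond the backbone N, CA, C, O, OXT). Glycine and residues
#' with no resolved side-chain atoms fall back to the CA position; a single
#' warning summarises how many residues used the fallback. With
#' `method = "allatom"` the centroid of all heavy atoms is used instead.
#'
#' @param unit a [structure_unit] carrying per-residue atoms.
#' @param method `"sidechain"` (default) or `"allatom"`.
#' @return The unit with `residues$x/y/z` and `residues$effective` filled.
#' @export
effective_atoms <- function(unit, method = c("sidechain", "allatom")) {
  method <- match.arg(method)
  unit$residues <- compute_effective(unit$residues, unit$atoms, method)
  unit
}

compute_effective <- function(res, at, method = "sidechain") {
  n_fallback <- 0L
  for (i in seq_len(nrow(res))) {
    ai <- at[at$res_idx == i, , drop = FALSE]
    if (nrow(ai) == 0) stop("residue with no atoms: ", residue_keys(res)[i])
    sel <- if (method == "allatom") rep(TRUE, nrow(ai))
           else !(ai$elety %in% .BACKBONE_ATOMS)
    if (method == "sidechain" && !any(sel)) {
      ca <- which(ai$elety == "CA")
      if (length(ca) == 0)
        stop("residue has neither side-chain atoms nor CA: ",
             residue_keys(res)[i])
      sel <- ca[1]
      n_fallback <- n_fallback + (res$aa[i] != "GLY")
      res$effective[i] <- "ca"
    } else {
      res$effective[i] <- if (method == "allatom") "allatom" else "sidechain"
    }
    res$x[i] <- mean(ai$x[sel]); res$y[i] <- mean(ai$y[sel])
    res$z[i] <- mean(ai$z[sel])
  }
  if (n_fallback > 0)
    warning(n_fallback,
            " non-glycine residue(s) without side-chain atoms; CA used")
  res
}

#' Intrinsic hydrophobicity scales
#'
#' Loads a per-residue hydrophobicity scale and min-max normalises it to
#' `[0, 1]` (most hydrophobic residue 1, least 0). The packaged default is
#' the Kyte-Doolittle hydropathy index; any two-column TSV
#' (`aa<TAB>value`, three-letter codes) or a named numeric vector over the
#' 20 standard residues may be supplied instead.
#'
#' @param scale `"kd"`, a path to a TSV file, or a named numeric vector.
#' @param normalize min-max normalise to `[0,1]` (default `TRUE`).
#' @return Named numeric vector over the 20 standard three-letter codes.
#' @export
hydro_scale <- function(scale = "kd", normalize = TRUE) {
  if (is.numeric(scale)) {
    v <- scale
  } else if (identical(scale, "kd")) {
    f <- system.file("extdata", "kyte_doolittle.tsv", package = "oildrop")
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    v <- stats::setNames(tab$value, tab$aa)
  } else if (is.character(scale) && file.exists(scale)) {
    tab <- utils::read.delim(scale, stringsAsFactors = FALSE)
    v <- stats::setNames(tab[[2]], tab[[1]])
  } else stop("unknown hydrophobicity scale: ", scale)
  missing <- setdiff(.STANDARD_AA, names(v))
  if (length(missing))
    stop("scale does not cover: ", paste(missing, collapse = ", "))
  v <- v[.STANDARD_AA]
  if (normalize) {
    rng <- range(v)
    if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
  }
  if (any(v < 0 | v > 1))
    stop("scale values must lie in [0,1] after normalisation")
  v
}

#' Assign intrinsic hydrophobicity to every residue
#'
#' Sets each residue's `H` from its amino-acid code under the given scale.
#' Idempotent and independent of residue order.
#'
#' @param unit a [structure_unit].
#' @param scale argument passed to [hydro_scale].
#' @return The unit with `residues$H` filled.
#' @export
assign_hydrophobicity <- function(unit, scale = "kd") {
  sc <- hydro_scale(scale)
  aa <- unit$residues$aa
  unknown <- setdiff(unique(aa), names(sc))
  if (length(unknown))
    stop("no hydrophobicity value for residue(s): ",
         paste(unknown, collapse = ", "))
  unit$residues$H <- unname(sc[aa])
  unit
}

#' Write a structure unit as a PDB file
#'
#' Emits fixed-column ATOM records (one per stored heavy atom) preceded by
#' one SSBOND record per annotated disulfide. Reloading with
#' [read_structure] reproduces residue count, ordering, chain partition,
#' SS bonds and coordinates to the 0.001-Angstrom PDB field precision.
#'
#' @param unit a [structure_unit].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(unit, path) {
  res <- unit$residues
  at <- unit$atoms
  stopifnot(nrow(res) >= 1, nrow(at) >= 1)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000) || any(xyz <= -1000))
    stop("coordinates outside the PDB fixed-column field width")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(pdb = NULL, file = tmp,
                   xyz = as.vector(t(xyz)),
                   type = rep("ATOM", nrow(at)),
                   resno = res$resno[at$res_idx],
                   resid = res$aa[at$res_idx],
                   eleno = seq_len(nrow(at)),
                   elety = at$elety,
                   chain = res$chain[at$res_idx],
                   insert = ifelse(res$icode[at$res_idx] == "", NA,
                                   res$icode[at$res_idx]),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  body <- readLines(tmp, warn = FALSE)
  ss_lines <- character()
  if (nrow(unit$ss_bonds) > 0) {
    b <- unit$ss_bonds
    ss_lines <- sprintf(
      "SSBOND %3d CYS %s %4d%1s   CYS %s %4d%1s",
      seq_len(nrow(b)), b$chain1, b$resno1,
      ifelse(b$icode1 == "", " ", b$icode1),
      b$chain2, b$resno2, ifelse(b$icode2 == "", " ", b$icode2))
  }
  writeLines(c(ss_lines, body), path)
  invisible(path)
}

#' Extract one or more chains as a new structure unit
#'
#' @param unit a [structure_unit].
#' @param chains chain identifiers to keep.
#' @return A [structure_unit] restricted to those chains (SS bonds with
#'   both endpoints inside are retained).
#' @export
subset_chains <- function(unit, chains) {
  keep <- which(unit$residues$chain %in% chains)
  if (length(keep) == 0) stop("no residues in chain(s): ",
                              paste(chains, collapse = ", "))
  subset_unit(unit, keep, source = paste0(unit$source, ":",
                                          paste(chains, collapse = "")))
}

subset_unit <- function(unit, idx, source = unit$source) {
  res <- unit$residues[idx, , drop = FALSE]
  at <- unit$atoms[unit$atoms$res_idx %in% idx, , drop = FALSE]
  at$res_idx <- match(at$res_idx, idx)
  rownames(res) <- NULL
  ss <- unit$ss_bonds
  if (nrow(ss) > 0) {
    key <- residue_keys(res)
    ok <- paste(ss$chain1, ss$resno1, ss$icode1) %in% key &
      paste(ss$chain2, ss$resno2, ss$icode2) %in% key
    ss <- ss[ok, , drop = FALSE]
  }
  structure_unit(res, at, ss, source = source, skipped = unit$skipped)
}
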