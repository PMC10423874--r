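# Assessment modes: individual units, chains in the context of a complex,
# protein-protein interfaces, disulfide-delimited fragments, domains,
# arbitrary selections and cross-form (bound interface on unbound chain).

#' Define a residue selection
#'
#' Selections name the residue subsets the model is assessed on: chains,
#' domains, interfaces, disulfide-delimited fragments, catalytic sets.
#' Members may be given as chains, inclusive author-numbering ranges, a set
#' of residue keys, or raw indices.
#'
#' @param name selection name.
#' @param chain chain id(s); alone, selects whole chains.
#' @param from,to inclusive residue-number range (author numbering) within
#'   `chain`; vectors describe several ranges (recycled against `chain`).
#' @param keys data frame with columns `chain`, `resno` and optionally
#'   `icode` listing members explicitly.
#' @param idx integer indices into the residue order of the target unit or
#'   profile.
#' @param kind one of `"chain"`, `"domain"`, `"interface"`,
#'   `"ss_fragment"`, `"custom"`.
#' @return An object of class `residue_selection`.
#' @export
residue_selection <- function(name, chain = NULL, from = NULL, to = NULL,
                              keys = NULL, idx = NULL,
                              kind = c("custom", "chain", "domain",
                                       "interface", "ss_fragment")) {
  kind <- match.arg(kind)
  structure(list(name = name, chain = chain, from = from, to = to,
                 keys = keys, idx = idx, kind = kind),
            class = "residue_selection")
}

#' @export
print.residue_selection <- function(x, ...) {
  cat(sprintf("Residue selection '%s' [%s]\n", x$name, x$kind))
  invisible(x)
}

# Resolve a selection to sorted residue indices of a structure_unit or of a
# fod profile. Every addressed residue must exist in the target.
selection_indices <- function(sel, target) {
  res <- if (inherits(target, "structure_unit")) target$residues
         else if (inherits(target, "fod")) target$profile
         else as.data.frame(target)
  key <- residue_keys(res)
  idx <- integer()
  if (!is.null(sel$idx)) idx <- c(idx, as.integer(sel$idx))
  if (!is.null(sel$keys)) {
    k <- sel$keys
    ic <- if ("icode" %in% names(k)) ifelse(is.na(k$icode), "", k$icode)
          else rep("", nrow(k))
    kk <- paste(k$chain, k$resno, ic)
    j <- match(kk, key)
    if (any(is.na(j)))
      stop("selection '", sel$name, "' addresses residues absent from the ",
           "target: ", paste(kk[is.na(j)], collapse = ", "))
    idx <- c(idx, j)
  }
  if (!is.null(sel$chain)) {
    if (is.null(sel$from)) {
      idx <- c(idx, which(res$chain %in% sel$chain))
    } else {
      n <- max(length(sel$chain), length(sel$from), length(sel$to))
      ch <- rep_len(sel$chain, n); fr <- rep_len(sel$from, n)
      to <- rep_len(sel$to, n)
      for (i in seq_len(n)) {
        hit <- which(res$chain == ch[i] & res$resno >= fr[i] &
                       res$resno <= to[i])
        if (length(hit) == 0)
          stop("selection '", sel$name, "': no residues in ", ch[i],
               " ", fr[i], "-", to[i])
        idx <- c(idx, hit)
      }
    }
  }
  idx <- sort(unique(idx))
  if (length(idx) == 0)
    stop("selection '", sel$name, "' is empty")
  if (any(idx < 1 | idx > nrow(res)))
    stop("selection '", sel$name, "' outside the residue index")
  idx
}

#' Status of a unit as an individual structural entity
#'
#' The 3D Gaussian spans this unit alone. Equivalent to `fod(unit)` with an
#' explicit mode label.
#'
#' @param unit a [structure_unit] (whole complex, single chain or domain).
#' @param params a [fod_params].
#' @param mode result label; default `"individual_chain"` for single
#'   chains, `"complex"` otherwise.
#' @return A `fod` object.
#' @export
status_individual <- function(unit, params = fod_params(), mode = NULL) {
  fod(unit, selection = NULL, params = params, mode = mode)
}

#' Status of a selection as a component of a complex
#'
#' The Gaussian and the pairwise interactions span the whole complex; the
#' T and O profiles are then restricted to the selection and renormalised
#' before RD and the optimal K are computed.
#'
#' @param complex a multi-residue [structure_unit].
#' @param sel a [residue_selection] within the complex.
#' @param params a [fod_params].
#' @param mode result label (default `"chain_in_complex"`).
#' @return A `fod` object.
#' @export
status_in_context <- function(complex, sel, params = fod_params(),
                              mode = "chain_in_complex") {
  fod(complex, selection = sel, params = params, mode = mode)
}

#' Identify protein-protein interface residues
#'
#' Residues whose effective atom lies within `cutoff` of any effective atom
#' in a different chain; the union over all chain pairs unless a specific
#' pair is requested.
#'
#' @param complex a [structure_unit] with at least two chains.
#' @param cutoff effective-atom distance, Angstrom (default 9, the
#'   interaction cutoff).
#' @param pair optional length-2 character vector restricting the scan to
#'   one chain pair.
#' @return A [residue_selection] of kind `"interface"`; its `idx` may be
#'   empty (no residues within the cutoff), in which case fitting it is an
#'   error and callers should report "no interface".
#' @export
interface_selection <- function(complex, cutoff = 9, pair = NULL) {
  res <- complex$residues
  chains <- unique(res$chain)
  if (length(chains) < 2)
    stop("interface requires a unit with at least two chains")
  keep <- seq_len(nrow(res))
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2, all(pair %in% chains))
    keep <- which(res$chain %in% pair)
  }
  pts <- as.matrix(res[keep, c("x", "y", "z")])
  ch <- res$chain[keep]
  d <- as.matrix(stats::dist(pts))
  cross <- outer(ch, ch, "!=")
  hit <- keep[apply(d <= cutoff & cross, 1, any)]
  residue_selection(name = if (is.null(pair)) "interface"
                           else paste0("interface:", pair[1], "-", pair[2]),
                    idx = hit, kind = "interface")
}

#' Selections for disulfide-delimited chain fragments
#'
#' One contiguous selection per intra-chain SS bond, spanning from the
#' lower- to the higher-numbered cysteine (in residue order). Inter-chain
#' SS bonds are skipped with a warning.
#'
#' @param unit a [structure_unit].
#' @return List of [residue_selection]s of kind `"ss_fragment"` (empty when
#'   the unit has no SS bonds).
#' @export
ss_fragment_selections <- function(unit) {
  b <- unit$ss_bonds
  out <- list()
  if (nrow(b) == 0) return(out)
  key <- residue_keys(unit$residues)
  for (i in seq_len(nrow(b))) {
    if (b$chain1[i] != b$chain2[i]) {
      warning("inter-chain SS bond skipped: ", b$chain1[i], b$resno1[i],
              "-", b$chain2[i], b$resno2[i])
      next
    }
    j1 <- match(paste(b$chain1[i], b$resno1[i], b$icode1[i]), key)
    j2 <- match(paste(b$chain2[i], b$resno2[i], b$icode2[i]), key)
    rng <- sort(c(j1, j2))
    out[[length(out) + 1]] <- residue_selection(
      name = sprintf("SS:%s%d-%d", b$chain1[i], min(b$resno1[i], b$resno2[i]),
                     max(b$resno1[i], b$resno2[i])),
      idx = rng[1]:rng[2], kind = "ss_fragment")
  }
  out
}

#' Status of bound-form interface residues on the unbound form
#'
#' Maps the residues of a bound-form interface selection onto the unbound
#' structure (identity on chain/residue number/insertion code by default,
#' or via per-chain residue-number offsets) and evaluates their fragment
#' status on the unbound profile. This is the "quoted value" convention of
#' bound/unbound comparisons: the status, in the free protein, of the
#' residues that will form the interface.
#'
#' @param unbound_fit `fod` fit of the unbound structure.
#' @param bound_fit `fod` fit (or profile-bearing object) of the bound
#'   structure the selection refers to.
#' @param bound_sel [residue_selection] on the bound structure.
#' @param offsets optional named numeric vector: residue-number offset to
#'   add per bound chain id, with names optionally remapping the chain
#'   (`c(A = 10)` adds 10 within chain A).
#' @param chain_map optional named character vector mapping bound chain ids
#'   to unbound chain ids.
#' @return A `fod` object with mode `"cross_form"`.
#' @export
cross_form_status <- function(unbound_fit, bound_fit, bound_sel,
                              offsets = NULL, chain_map = NULL) {
  stopifnot(inherits(unbound_fit, "fod"))
  bprof <- if (inherits(bound_fit, "fod")) bound_fit$profile
           else as.data.frame(bound_fit)
  bidx <- selection_indices(bound_sel, bprof)
  keys <- bprof[bidx, c("chain", "resno", "icode"), drop = FALSE]
  if (!is.null(offsets)) {
    for (ch in names(offsets))
      keys$resno[keys$chain == ch] <- keys$resno[keys$chain == ch] +
        offsets[[ch]]
  }
  if (!is.null(chain_map)) {
    hit <- keys$chain %in% names(chain_map)
    keys$chain[hit] <- unname(chain_map[keys$chain[hit]])
  }
  ukey <- residue_keys(unbound_fit$profile)
  j <- match(paste(keys$chain, keys$resno, keys$icode), ukey)
  if (any(is.na(j)))
    stop("bound-interface residues with no unbound counterpart: ",
         paste(paste(keys$chain, keys$resno)[is.na(j)], collapse = ", "))
  fragment_status(unbound_fit, j, mode = "cross_form")
}

#' Read named selections from a YAML config
#'
#' The file holds a list of selections, each with `name`, optional `kind`,
#' and members as `chain` plus inclusive `from`/`to` residue ranges (author
#' numbering), e.g.
#' ```yaml
#' - name: core_domain
#'   kind: domain
#'   chain: A
#'   from: 94
#'   to: 289
#' ```
#'
#' @param path YAML file path.
#' @return List of [residue_selection]s.
#' @export
read_selections <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    residue_selection(name = s$name,
                      chain = s$chain,
                      from = if (is.null(s$from)) NULL else as.integer(s$from),
                      to = if (is.null(s$to)) NULL else as.integer(s$to),
                      kind = if (is.null(s$kind)) "custom" else s$kind)
  })
}
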