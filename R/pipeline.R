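# End-to-end orchestration: analyze one structure in every applicable
# assessment mode, batch over a manifest, and write per-residue and
# per-mode reports.

#' Analyze a structure in all applicable assessment modes
#'
#' Runs the full fuzzy-oil-drop assessment: the whole unit (complex when
#' multi-chain), every chain as an individual structural unit, every chain
#' as a component of the complex, the inter-chain interface, user-supplied
#' domains, disulfide-delimited fragments and any custom selections. Modes
#' that do not apply (e.g. interface on a monomer) or that degenerate are
#' recorded in `skipped` with their reason rather than failing the report.
#'
#' @param x a PDB file path or a [structure_unit].
#' @param params a [fod_params].
#' @param domains list of [residue_selection]s (kind `"domain"`), each
#'   analyzed as an individual structural unit.
#' @param selections list of [residue_selection]s evaluated as fragments of
#'   the whole-unit profile (catalytic sets, arbitrary ranges), or a path
#'   to a YAML file for [read_selections].
#' @param interface compute the interface mode (default `TRUE`).
#' @return An object of class `fod_report`: list with `source`, `fits`
#'   (named list of `fod` objects), `skipped` (named reasons), `profile`
#'   (whole-unit per-residue table with an `interface` flag) and `params`.
#' @export
analyze <- function(x, params = fod_params(), domains = NULL,
                    selections = NULL, interface = TRUE) {
  unit <- if (inherits(x, "structure_unit")) x else read_structure(x)
  if (any(is.na(unit$residues$H)))
    unit <- assign_hydrophobicity(unit, params$scale)
  if (is.character(selections)) selections <- read_selections(selections)

  chains <- unique(unit$residues$chain)
  multi <- length(chains) > 1
  fits <- list()
  skipped <- character()

  add_fit <- function(name, expr) {
    f <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (inherits(f, "fod")) fits[[name]] <<- f
    else skipped[[name]] <<- f
    invisible(NULL)
  }

  add_fit(if (multi) "complex" else "individual",
          fod(unit, params = params,
              mode = if (multi) "complex" else "individual_chain"))
  main_fit <- if (length(fits)) fits[[1]] else NULL

  chain_fits <- list()
  for (ch in chains) {
    nm <- paste0("individual:", ch)
    add_fit(nm, fod(subset_chains(unit, ch), params = params,
                    mode = "individual_chain"))
    if (!is.null(fits[[nm]])) chain_fits[[ch]] <- fits[[nm]]
    if (multi)
      add_fit(paste0("in_complex:", ch),
              fod(unit, residue_selection(paste0("chain ", ch), chain = ch,
                                          kind = "chain"),
                  params = params, mode = "chain_in_complex"))
  }

  iface_idx <- integer()
  if (interface && multi) {
    sel <- interface_selection(unit, cutoff = params$interface_cutoff)
    iface_idx <- sel$idx
    if (length(sel$idx) >= 2) add_fit("interface",
                                      fod(unit, sel, params = params,
                                          mode = "interface"))
    else skipped[["interface"]] <- "no interface within cutoff"
  } else if (interface && !multi) {
    skipped[["interface"]] <- "single chain: no interface"
  }

  for (d in domains %||% list())
    add_fit(paste0("domain:", d$name),
            fod(subset_unit(unit, selection_indices(d, unit),
                            source = paste0(unit$source, ":", d$name)),
                params = params, mode = "domain"))

  for (ssel in ss_fragment_selections(unit)) {
    ch <- unit$residues$chain[ssel$idx[1]]
    target <- chain_fits[[ch]]
    if (is.null(target)) next
    keys <- unit$residues[ssel$idx, c("chain", "resno", "icode"),
                          drop = FALSE]
    add_fit(ssel$name,
            fragment_status(target,
                            residue_selection(ssel$name, keys = keys,
                                              kind = "ss_fragment"),
                            mode = "fragment"))
  }

  for (s in selections %||% list())
    if (!is.null(main_fit))
      add_fit(paste0("selection:", s$name),
              fragment_status(main_fit, s, mode = "fragment"))

  profile <- if (!is.null(main_fit)) main_fit$profile else NULL
  if (!is.null(profile))
    profile$interface <- seq_len(nrow(profile)) %in% iface_idx

  structure(list(source = unit$source, fits = fits, skipped = skipped,
                 profile = profile, params = params),
            class = "fod_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fod_report <- function(x, ...) {
  cat("Fuzzy-oil-drop report:", x$source, "\n")
  print(as.data.frame(x), digits = 3)
  if (length(x$skipped)) {
    cat("Skipped modes:\n")
    for (nm in names(x$skipped)) cat("  ", nm, ": ", x$skipped[[nm]], "\n",
                                     sep = "")
  }
  invisible(x)
}

#' Combined table of a report's statuses
#'
#' One row per assessed mode with the columns of the published tables:
#' unit, mode, N, D(O|T), D(O|R), RD, K, D(O|M).
#'
#' @param x a `fod_report`.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.fod_report <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  rows <- lapply(names(x$fits), function(nm) {
    s <- x$fits[[nm]]$status
    data.frame(unit = x$source, entry = nm, mode = s$mode,
               n = s$n_residues, d_ot = s$d_ot, d_or = s$d_or,
               rd = s$rd, k = s$k_opt, d_om = s$d_om,
               hydrophobic_core = s$hydrophobic_core,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report to disk
#'
#' Emits `<stem>_report.json` (per-mode statuses, Gaussian sigmas, skipped
#' modes; floating values at fixed precision so reruns are byte-identical)
#' and `<stem>_profile.tsv` (per-residue chain, residue number, amino acid,
#' T, O, R, M and interface flag).
#'
#' @param report a `fod_report`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem; defaults to a sanitised source id.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir, stem = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- stem %||% gsub("[^A-Za-z0-9_.-]+", "_", report$source)
  jpath <- file.path(dir, paste0(stem, "_report.json"))
  tpath <- file.path(dir, paste0(stem, "_profile.tsv"))
  statuses <- lapply(report$fits, function(f) {
    s <- f$status
    s$sigma <- if (!is.null(f$encapsulation)) round(f$encapsulation$sigma, 6)
    lapply(s, function(v) if (is.numeric(v)) round(v, 6) else v)
  })
  jsonlite::write_json(list(source = report$source, statuses = statuses,
                            skipped = as.list(report$skipped)),
                       jpath, auto_unbox = TRUE, digits = NA)
  if (!is.null(report$profile)) {
    prof <- report$profile
    num <- vapply(prof, is.numeric, TRUE) & !names(prof) %in% "resno"
    prof[num] <- lapply(prof[num], function(v) round(v, 6))
    utils::write.table(prof, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(json = jpath, profile = tpath))
}

#' Batch analysis over a manifest
#'
#' Analyzes every entry of a manifest (a data frame or TSV file with
#' columns `id` and `path`), writes one report per entry plus a combined
#' TSV of all statuses. Failures are isolated: a bad entry is flagged in
#' the combined table with its error message and does not stop the run.
#'
#' @param manifest data frame or TSV path with columns `id`, `path`.
#' @param out_dir output directory.
#' @param params a [fod_params].
#' @return The combined data frame, invisibly (also written to
#'   `combined.tsv`).
#' @export
batch <- function(manifest, out_dir, params = fod_params()) {
  if (is.character(manifest))
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "path") %in% names(manifest)))
  if (nrow(manifest) == 0) stop("empty manifest")
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]
    out <- tryCatch({
      rep <- analyze(manifest$path[i], params = params)
      write_report(rep, out_dir, stem = id)
      df <- as.data.frame(rep)
      df$unit <- id
      df$failed <- FALSE
      df$error <- ""
      df
    }, error = function(e) {
      data.frame(unit = id, entry = NA, mode = NA, n = NA, d_ot = NA,
                 d_or = NA, rd = NA, k = NA, d_om = NA,
                 hydrophobic_core = NA, failed = TRUE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- out
  }
  combined <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- vapply(combined, is.numeric, TRUE)
  combined[num] <- lapply(combined[num], function(v) round(v, 6))
  utils::write.table(combined, file.path(out_dir, "combined.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(combined)
}

#' Fetch a structure from the Protein Data Bank
#'
#' Downloads `<id>.pdb` from RCSB. Network access is optional and nothing
#' else in the package requires it; all tests run on synthetic fixtures.
#'
#' @param id 4-character PDB accession.
#' @param destdir directory for the downloaded file.
#' @param quiet suppress download progress.
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(id, destdir = tempdir(), quiet = TRUE) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", id))
  dest <- file.path(destdir, paste0(toupper(id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
    status <- tryCatch(utils::download.file(url, dest, quiet = quiet),
                       error = function(e) {
                         unlink(dest)
                         stop("cannot fetch ", id, " from RCSB: ",
                              conditionMessage(e), call. = FALSE)
                       })
    if (!identical(status, 0L)) {
      unlink(dest)
      stop("cannot fetch ", id, " from RCSB (status ", status, ")")
    }
  }
  dest
}
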