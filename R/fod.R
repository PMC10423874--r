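# The fitting interface: fod() fits the fuzzy-oil-drop / FOD-M model to a
# structure unit (optionally restricted to a selection within a larger
# complex) and returns a classed object with the usual accessor methods.

#' Model parameters for a fuzzy-oil-drop fit
#'
#' @param cutoff hydrophobic-interaction cutoff, Angstrom (default 9).
#' @param contact contact-function form: `"sigmoid"` (default) or `"ramp"`.
#' @param pad padding added to each Gaussian half-extent, Angstrom.
#' @param sigma_floor smallest allowed half-extent, Angstrom.
#' @param k_max,k_step grid for the K search (defaults 10 and 0.01).
#' @param scale intrinsic hydrophobicity scale (see [hydro_scale]).
#' @param interface_cutoff effective-atom distance defining interface
#'   residues; defaults to `cutoff`.
#' @return A list of class `fod_params`.
#' @export
fod_params <- function(cutoff = 9, contact = c("sigmoid", "ramp"), pad = 0,
                       sigma_floor = 1, k_max = 10, k_step = 0.01,
                       scale = "kd", interface_cutoff = NULL) {
  contact <- match.arg(contact)
  stopifnot(cutoff > 0, pad >= 0, sigma_floor > 0, k_max >= 0, k_step > 0)
  structure(list(cutoff = cutoff, contact = contact, pad = pad,
                 sigma_floor = sigma_floor, k_max = k_max, k_step = k_step,
                 scale = scale,
                 interface_cutoff = if (is.null(interface_cutoff)) cutoff
                                    else interface_cutoff),
            class = "fod_params")
}

#' Fit the fuzzy-oil-drop model to a structure unit
#'
#' Orients and encapsulates the unit in a 3D Gaussian, computes the
#' theoretical (T), observed (O) and uniform reference (R) hydrophobicity
#' profiles, the relative-distance statistic RD, and the optimal
#' environment parameter K of the modified target M(K) together with
#' `D(O|M(K*))`.
#'
#' With a `selection`, the Gaussian and the interactions still span the
#' whole unit (the chain or fragment is assessed "as a component of the
#' complex"): T and O are computed over all residues, then restricted to
#' the selection and renormalised before RD and K are evaluated.
#'
#' @param unit a [structure_unit]. If `H` is unassigned, the scale in
#'   `params` is applied first.
#' @param selection optional [residue_selection] restricting the assessment
#'   while the field spans the whole unit.
#' @param params a [fod_params] list.
#' @param mode label stored in the result (e.g. `"complex"`,
#'   `"individual_chain"`, `"chain_in_complex"`, `"interface"`,
#'   `"domain"`); defaults to `"complex"` for multi-chain units without a
#'   selection, `"individual_chain"` for single chains, and
#'   `"chain_in_complex"` when a selection is given.
#' @return An object of class `fod`: list with `status` (fields `d_ot`,
#'   `d_or`, `rd`, `k_opt`, `d_om`, `n_residues`, `mode`,
#'   `hydrophobic_core`), `profile` (per-residue data frame with columns
#'   `chain`, `resno`, `icode`, `aa`, `T`, `O`, `R`, `M`), `encapsulation`,
#'   `params` and `source`.
#' @seealso [fragment_status()], [status_individual()],
#'   [status_in_context()], [interface_selection()]
#' @export
fod <- function(unit, selection = NULL, params = fod_params(), mode = NULL) {
  stopifnot(inherits(unit, "structure_unit"))
  if (n_residues(unit) < 2)
    stop("at least two residues are required")
  if (any(is.na(unit$residues$H)))
    unit <- assign_hydrophobicity(unit, params$scale)

  pts <- as.matrix(unit$residues[, c("x", "y", "z")])
  tp <- unit_t_profile(unit, pad = params$pad, floor = params$sigma_floor)
  Tfull <- tp$T
  Ofull <- o_profile(pts, unit$residues$H, cutoff = params$cutoff,
                     form = if (params$contact == "sigmoid") "sigmoid"
                            else "ramp")

  if (is.null(mode)) {
    mode <- if (!is.null(selection)) "chain_in_complex"
            else if (length(unique(unit$residues$chain)) > 1) "complex"
            else "individual_chain"
  }

  idx <- seq_len(nrow(pts))
  if (!is.null(selection)) {
    idx <- selection_indices(selection, unit)
    if (length(idx) < 2)
      stop("degenerate selection: fewer than two residues")
  }
  res <- unit$residues[idx, c("chain", "resno", "icode", "aa"), drop = FALSE]
  rownames(res) <- NULL

  fit_from_profiles(Tfull[idx], Ofull[idx], res, params, mode,
                    source = unit$source, encapsulation = tp$enc,
                    selection_name = if (is.null(selection)) NULL
                                     else selection$name)
}

# Core of every assessment mode: renormalise the (possibly sliced) T and O,
# compute RD and the optimal K, assemble the classed result.
fit_from_profiles <- function(Tv, Ov, residues, params, mode, source,
                              encapsulation = NULL, selection_name = NULL) {
  if (sum(Ov) <= 0)
    stop("degenerate selection: zero observed-hydrophobicity mass")
  Tv <- floor_norm(Tv)
  Ov <- floor_norm(Ov)
  st <- rd_statistic(Ov, Tv)
  ko <- optimize_k(Ov, Tv, k_max = params$k_max, step = params$k_step)
  Mv <- m_profile(Tv, ko$k_opt)
  profile <- cbind(residues,
                   data.frame(T = Tv, O = Ov, R = 1 / length(Tv), M = Mv))
  status <- list(d_ot = st$d_ot, d_or = st$d_or, rd = st$rd,
                 k_opt = ko$k_opt, k_rounded = ko$k_rounded,
                 d_om = ko$d_om, n_residues = length(Tv), mode = mode,
                 hydrophobic_core = st$hydrophobic_core)
  structure(list(status = status, profile = profile,
                 encapsulation = encapsulation, params = params,
                 source = source, selection = selection_name),
            class = "fod")
}

#' Status of a fragment of an existing profile
#'
#' Slices the T and O profiles of a fitted unit at the given selection,
#' renormalises them, and recomputes RD and the optimal K. This is the
#' assessment used for disulfide-delimited fragments, catalytic sets,
#' interface residues and any other sub-profile: the field is the one
#' fitted to the whole unit, only the compared residues change. Applied to
#' the full index it reproduces the unit's status exactly.
#'
#' @param fit a `fod` object.
#' @param selection a [residue_selection] (resolved against the fit's
#'   profile rows), or an integer vector of profile row indices.
#' @param mode label for the result (default `"fragment"`).
#' @return A `fod` object with `n_residues = length(selection)`.
#' @export
fragment_status <- function(fit, selection, mode = "fragment") {
  stopifnot(inherits(fit, "fod"))
  idx <- if (is.numeric(selection)) as.integer(selection)
         else selection_indices(selection, fit)
  if (length(idx) < 2)
    stop("degenerate selection: fewer than two residues")
  if (any(idx < 1 | idx > nrow(fit$profile)))
    stop("selection outside the profile index")
  idx <- sort(unique(idx))
  res <- fit$profile[idx, c("chain", "resno", "icode", "aa"), drop = FALSE]
  rownames(res) <- NULL
  fit_from_profiles(fit$profile$T[idx], fit$profile$O[idx], res,
                    fit$params, mode, source = fit$source,
                    encapsulation = fit$encapsulation,
                    selection_name = if (is.numeric(selection)) NULL
                                     else selection$name)
}

#' @export
print.fod <- function(x, ...) {
  s <- x$status
  cat(sprintf("Fuzzy-oil-drop fit: %s%s [%s]\n", x$source,
              if (!is.null(x$selection)) paste0(" / ", x$selection) else "",
              s$mode))
  cat(sprintf("  N = %d residues\n", s$n_residues))
  cat(sprintf("  D(O|T) = %.4f bits   D(O|R) = %.4f bits\n", s$d_ot, s$d_or))
  cat(sprintf("  RD = %.3f  (%s)\n", s$rd,
              if (s$hydrophobic_core) "hydrophobic core present, RD < 0.5"
              else "no hydrophobic core, RD >= 0.5"))
  cat(sprintf("  K = %.2f   D(O|M(K)) = %.4f bits\n", s$k_opt, s$d_om))
  invisible(x)
}

#' @export
summary.fod <- function(object, ...) {
  s <- object$status
  out <- data.frame(source = object$source,
                    selection = if (is.null(object$selection)) NA_character_
                                else object$selection,
                    mode = s$mode, n = s$n_residues,
                    d_ot = s$d_ot, d_or = s$d_or, rd = s$rd,
                    k = s$k_opt, d_om = s$d_om,
                    hydrophobic_core = s$hydrophobic_core,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.fod", "data.frame")
  out
}

#' @export
coef.fod <- function(object, ...) {
  c(RD = object$status$rd, K = object$status$k_opt)
}

#' @export
fitted.fod <- function(object, ...) {
  stats::setNames(object$profile$M,
                  paste0(object$profile$chain, object$profile$resno,
                         object$profile$icode))
}

#' @export
residuals.fod <- function(object, type = c("modified", "theoretical"), ...) {
  type <- match.arg(type)
  ref <- if (type == "modified") object$profile$M else object$profile$T
  stats::setNames(object$profile$O - ref,
                  paste0(object$profile$chain, object$profile$resno,
                         object$profile$icode))
}

#' Plot T, O and M hydrophobicity profiles
#'
#' @param x a `fod` object.
#' @param ... further arguments passed to [graphics::matplot].
#' @export
plot.fod <- function(x, ...) {
  p <- x$profile
  graphics::matplot(seq_len(nrow(p)), cbind(p$T, p$O, p$M), type = "l",
                    lty = c(1, 1, 2), col = c("blue", "red", "darkgreen"),
                    xlab = "residue index", ylab = "hydrophobicity",
                    main = sprintf("%s [%s]  RD = %.3f, K = %.2f", x$source,
                                   x$status$mode, x$status$rd,
                                   x$status$k_opt), ...)
  graphics::legend("topright", legend = c("T", "O", sprintf("M(K = %.2f)",
                                                            x$status$k_opt)),
                   lty = c(1, 1, 2), col = c("blue", "red", "darkgreen"),
                   bty = "n")
  invisible(x)
}
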