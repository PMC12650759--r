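#' Analyze a structural unit with its own Gaussian envelope
#'
#' Unit mode: the selected residues are encapsulated in their own fitted 3D
#' Gaussian, and the T, O and R profiles are computed over those residues
#' only (pairwise interaction sums restricted to the unit). RD and K are
#' then derived from the profiles.
#'
#' @param structure An `fodm_structure`.
#' @param selection Optional [fodm_selection()] (or interval string) carving
#'   the unit out of `structure`; default: the whole structure.
#' @param cutoff Levitt interaction cutoff, Angstrom (default 9).
#' @param k_grid K search grid (default 0 to 10 by 0.1).
#' @param include_self Include self-interaction in O (default `FALSE`).
#' @param label Unit label; defaults to the selection name or source label.
#' @return An `fodm_result` with `mode = "unit"`, carrying the residues
#'   table, the fitted envelope and the four profiles.
#' @export
analyze_unit <- function(structure, selection = NULL, cutoff = 9,
                         k_grid = (0:100) / 10, include_self = FALSE,
                         label = NULL) {
  if (!is.null(selection)) {
    structure <- apply_selection(structure, selection)
    if (is.null(label)) label <- attr(structure, "selection_name")
  }
  if (is.null(label)) label <- attr(structure, "source_label") %||% "unit"
  if (nrow(structure) < 3) stop("unit '", label, "' has fewer than 3 residues")
  env <- fit_envelope(structure)
  t <- theoretical_profile(structure, env)
  o <- observed_profile(structure, cutoff = cutoff, include_self = include_self)
  res <- fodm_result(t, o, k_grid = k_grid, mode = "unit", label = label)
  res$residues <- tibble::as_tibble(structure)
  res$envelope <- env
  res$cutoff <- cutoff
  res
}

#' Analyze a fragment of an already-analyzed unit
#'
#' Fragment mode: no new envelope is fitted. The enclosing unit's T and O
#' profiles are restricted to the fragment's residues and renormalized, R is
#' rebuilt as uniform over the fragment, and RD and K are recomputed — the
#' fragment's contribution to the unit's hydrophobicity organization.
#'
#' @param unit_result An `fodm_result` from [analyze_unit()].
#' @param fragment An [fodm_selection()] (or interval string) resolved
#'   against the unit's residues, or an integer/logical index vector.
#' @param k_grid K search grid.
#' @param label Fragment label.
#' @return An `fodm_result` with `mode = "fragment"`.
#' @export
analyze_fragment <- function(unit_result, fragment,
                             k_grid = (0:100) / 10, label = NULL) {
  stopifnot(inherits(unit_result, "fodm_result"))
  if (is.null(unit_result$residues)) stop("unit result carries no residue table")
  if (is.numeric(fragment) || is.logical(fragment)) {
    idx <- if (is.logical(fragment)) which(fragment) else as.integer(fragment)
    if (is.null(label)) label <- "fragment"
  } else {
    if (!inherits(fragment, "fodm_selection")) {
      fragment <- fodm_selection(label %||% "fragment", fragment)
    }
    idx <- match_indices(unit_result$residues, fragment)
    if (is.null(label)) label <- fragment$name
  }
  res <- fragment_result(unit_result$profiles$t, unit_result$profiles$o, idx,
                         k_grid = k_grid, label = label)
  res$residues <- unit_result$residues[idx, , drop = FALSE]
  res$parent <- unit_result$label
  res
}

# Resolve a selection against a residue table, returning row indices.
match_indices <- function(residues, selection) {
  iv <- selection$intervals
  hit <- rep(FALSE, nrow(residues))
  for (i in seq_len(nrow(iv))) {
    if (is.na(iv$start[i])) {
      hit <- hit | residues$chain == iv$chain[i]
    } else {
      hit <- hit | (residues$chain == iv$chain[i] &
                      residues$resno >= iv$start[i] &
                      residues$resno <= iv$end[i])
    }
  }
  if (!any(hit)) {
    stop("fragment '", selection$name, "' is not contained in the unit")
  }
  which(hit)
}

#' Flag per-residue excess and deficit of observed hydrophobicity
#'
#' Compares O to the band spanned by T and M: a residue is in local
#' `excess` if its observed hydrophobicity exceeds both targets, in
#' `deficit` if it falls below both, and `conformant` otherwise. The three
#' flags partition the unit's residues.
#'
#' @param result An `fodm_result`.
#' @return The per-residue tibble of [tidy.fodm_result()] with an added
#'   `status` factor column.
#' @export
annotate_status <- function(result) {
  out <- tidy(result)
  hi <- pmax(out$t, out$m)
  lo <- pmin(out$t, out$m)
  out$status <- factor(
    dplyr::case_when(out$o > hi ~ "excess",
                     out$o < lo ~ "deficit",
                     TRUE ~ "conformant"),
    levels = c("deficit", "conformant", "excess"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
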