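#' Read a PDB file into per-residue effective-atom records
#'
#' Collapses every polymer residue to a single "effective atom": the
#' arithmetic mean position of its non-hydrogen atoms. The residue's mean
#' heavy-atom B-factor and its intrinsic hydrophobicity (from `scale`,
#' min-max normalized) are attached, giving the table every downstream
#' profile computation consumes.
#'
#' Waters, ligands and other HETATM content are excluded unless their
#' residue names are listed in `keep_hetatm`. For alternate conformations
#' the blank/'A' altloc is kept; where a residue atom exists only in other
#' altlocs the highest-occupancy record wins (ties broken by altloc letter).
#' Only one coordinate model is read (`model`, default the first).
#'
#' @param pdb_source Path to a PDB file (anything `bio3d::read.pdb()`
#'   accepts).
#' @param scale A hydrophobicity scale from [fodm_scale()] or
#'   [fodm_scale_from_file()].
#' @param model Model index for multi-model files; default 1.
#' @param keep_hetatm Character vector of HETATM residue names to retain
#'   (e.g. modified residues); default none.
#' @param unknown_h Optional fallback normalized hydrophobicity for residue
#'   names absent from the scale; by default such residues are an error.
#' @return A tibble of class `fodm_structure`: one row per residue with
#'   columns `chain`, `resno`, `ins`, `resname`, `x`, `y`, `z`, `h`
#'   (intrinsic hydrophobicity), `b` (mean B-factor, A^2). The source label
#'   is kept in `attr(, "source_label")`.
#' @export
read_structure <- function(pdb_source, scale = fodm_scale(), model = 1,
                           keep_hetatm = character(), unknown_h = NULL) {
  pdb <- bio3d::read.pdb(pdb_source, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    stop("model index ", model, " not present (file has ", n_models, " model(s))")
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]

  keep <- atom$type == "ATOM" |
    (atom$type == "HETATM" & atom$resid %in% toupper(keep_hetatm))
  atom <- atom[keep & !is_hydrogen(atom), , drop = FALSE]
  if (nrow(atom) == 0) stop("no polymer heavy atoms found in ", format(pdb_source)[1])

  atom <- resolve_altloc(atom)

  atom$ins <- ifelse(is.na(atom$insert), "", atom$insert)
  atom$chain <- ifelse(is.na(atom$chain), " ", atom$chain)
  key <- paste(atom$chain, atom$resno, atom$ins, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])          # file order of first appearance
  atom$b[is.na(atom$b)] <- 0
  sums <- rowsum(atom[, c("x", "y", "z", "b")], grp)   # groups sort as 1..G
  cnt <- tabulate(grp)

  res <- tibble::tibble(
    chain   = atom$chain[first],
    resno   = atom$resno[first],
    ins     = atom$ins[first],
    resname = atom$resid[first],
    x = sums$x / cnt, y = sums$y / cnt, z = sums$z / cnt, b = sums$b / cnt
  )
  res$h <- scale_lookup(scale, res$resname, fallback = unknown_h)
  res <- res[, c("chain", "resno", "ins", "resname", "x", "y", "z", "h", "b")]
  new_structure(res,
                source_label = if (is.character(pdb_source)) basename(pdb_source) else "pdb",
                scale_name = attr(scale, "scale_name"))
}

new_structure <- function(tbl, source_label = "synthetic", scale_name = NA_character_) {
  tbl <- tibble::as_tibble(tbl)
  if (!"ins" %in% names(tbl)) tbl$ins <- ""
  stopifnot(all(c("chain", "resno", "resname", "x", "y", "z", "h", "b") %in% names(tbl)),
            all(tbl$h >= 0), all(tbl$b >= 0))
  key <- paste(tbl$chain, tbl$resno, tbl$ins)
  if (anyDuplicated(key)) stop("duplicated (chain, residue number, insertion) keys")
  attr(tbl, "source_label") <- source_label
  attr(tbl, "scale_name") <- scale_name
  class(tbl) <- unique(c("fodm_structure", class(tbl)))
  tbl
}

is_hydrogen <- function(atom) {
  elesy <- toupper(trimws(ifelse(is.na(atom$elesy), "", atom$elesy)))
  known <- elesy != ""
  h <- elesy %in% c("H", "D")
  # fall back to the atom-name convention when the element column is absent
  name1 <- sub("^[0-9]*", "", toupper(trimws(atom$elety)))
  h[!known] <- substr(name1[!known], 1, 1) %in% c("H", "D")
  h
}

# One row per (residue, atom name): prefer blank/'A' altloc, then highest
# occupancy, then altloc letter.
resolve_altloc <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  if (all(alt %in% c("", "A"))) return(atom)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  grp <- paste(atom$chain, atom$resno, ifelse(is.na(atom$insert), "", atom$insert),
               atom$elety, sep = "\r")
  pref <- order(!(alt %in% c("", "A")),   # blank/'A' first
                -occ,                      # then highest occupancy
                alt)                       # then letter
  keep <- pref[!duplicated(grp[pref])]
  atom[sort(keep), , drop = FALSE]         # restore file order
}

#' Define a named residue selection
#'
#' A selection is a named union of inclusive author-numbered residue ranges,
#' optionally restricted per chain, used to carve complexes, chains, domains
#' and beta-sheets out of a structure.
#'
#' @param name Selection label (used in error messages and reports).
#' @param intervals Either a data frame with columns `chain`, `start`, `end`,
#'   or a compact string such as `"A:112-121,A:141-145"`. `"A:*"` selects a
#'   whole chain; `"chains=A,B"` selects the union of whole chains.
#' @param role One of `"complex"`, `"chain"`, `"domain"`, `"beta_sheet"`,
#'   `"rcl"`, `"custom"`.
#' @return An object of class `fodm_selection`.
#' @examples
#' fodm_selection("sheetA", "A:112-121,A:141-145,A:182-190,A:291-298,A:330-340",
#'                role = "beta_sheet")
#' @export
fodm_selection <- function(name, intervals,
                           role = c("custom", "complex", "chain", "domain",
                                    "beta_sheet", "rcl")) {
  role <- match.arg(role)
  iv <- as_intervals(intervals)
  stopifnot(nrow(iv) >= 1, all(iv$start <= iv$end | is.na(iv$start)))
  structure(list(name = name, intervals = iv, role = role),
            class = "fodm_selection")
}

as_intervals <- function(x) {
  if (is.data.frame(x)) {
    return(tibble::as_tibble(x)[, c("chain", "start", "end")])
  }
  stopifnot(is.character(x), length(x) == 1)
  x <- gsub(" ", "", x)
  if (grepl("^chains=", x)) {
    chains <- strsplit(sub("^chains=", "", x), ",")[[1]]
    return(tibble::tibble(chain = chains, start = NA_integer_, end = NA_integer_))
  }
  parts <- strsplit(x, ",")[[1]]
  purrr::map_dfr(parts, function(p) {
    m <- regmatches(p, regexec("^([^:]+):(\\*|(-?[0-9]+)-(-?[0-9]+))$", p))[[1]]
    if (length(m) == 0) stop("cannot parse interval: '", p, "'")
    if (m[3] == "*") {
      tibble::tibble(chain = m[2], start = NA_integer_, end = NA_integer_)
    } else {
      tibble::tibble(chain = m[2], start = as.integer(m[4]), end = as.integer(m[5]))
    }
  })
}

#' @export
print.fodm_selection <- function(x, ...) {
  cat("<fodm_selection> ", x$name, " [", x$role, "]\n", sep = "")
  print(x$intervals)
  invisible(x)
}

#' Apply a selection to a structure
#'
#' Keeps the residues whose (chain, author residue number) fall inside any of
#' the selection's inclusive intervals, preserving file order. Residue
#' numbers covered by an interval but absent from the model (crystallographic
#' gaps) are skipped; their count is available as `attr(, "n_missing")`.
#'
#' @param structure An `fodm_structure` tibble.
#' @param selection An [fodm_selection()], or anything its `intervals`
#'   argument accepts (coerced with role `"custom"`).
#' @return The selected `fodm_structure`; errors if the selection resolves to
#'   no residues.
#' @export
apply_selection <- function(structure, selection) {
  if (!inherits(selection, "fodm_selection")) {
    selection <- fodm_selection("selection", selection)
  }
  iv <- selection$intervals
  hit <- rep(FALSE, nrow(structure))
  n_named <- 0L
  for (i in seq_len(nrow(iv))) {
    if (is.na(iv$start[i])) {                 # whole chain
      hit <- hit | structure$chain == iv$chain[i]
    } else {
      hit <- hit | (structure$chain == iv$chain[i] &
                      structure$resno >= iv$start[i] &
                      structure$resno <= iv$end[i])
      n_named <- n_named + (iv$end[i] - iv$start[i] + 1L)
    }
  }
  if (!any(hit)) {
    stop("selection '", selection$name, "' resolves to no residues")
  }
  out <- structure[hit, , drop = FALSE]
  n_missing <- if (n_named > 0) max(0L, n_named - sum(hit)) else 0L
  out <- new_structure(out,
                       source_label = attr(structure, "source_label"),
                       scale_name = attr(structure, "scale_name"))
  attr(out, "selection_name") <- selection$name
  attr(out, "n_missing") <- n_missing
  out
}

#' Write a minimal PDB fixture for a residue-level structure
#'
#' Emits one CA-like ATOM record per residue at the effective-atom position,
#' occupancy 1.00 and the mean B-factor in the B column, so that
#' `read_structure(write_fixture_pdb(x))` round-trips coordinates within the
#' PDB column precision (1e-3 A).
#'
#' @param structure An `fodm_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(structure, path) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000) ) {
    stop("coordinates exceed the fixed-column PDB width (|coord| >= 1e4 A)")
  }
  if (any(structure$b >= 1000)) stop("B-factors exceed the PDB column width")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   resno = structure$resno,
                   chain = structure$chain,
                   insert = ifelse(structure$ins == "", NA, structure$ins),
                   resid = structure$resname,
                   elety = rep("CA", nrow(structure)),
                   o = rep(1, nrow(structure)),
                   b = structure$b)
  invisible(path)
}
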