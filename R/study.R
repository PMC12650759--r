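#' Run a multi-form hydrophobicity study
#'
#' Drives the full analysis over a set of structures and a declarative
#' study configuration: for every configured form it reports the complex
#' (when a protease partner is configured), each chain group both as a
#' fragment of the complex and as an individual unit, each domain both
#' in-chain (fragment mode) and as an individual unit, every configured
#' sheet (with and without incorporated strands, as separate entries), the
#' surface-loop selection, and per-domain B-factor correlations. Rows that
#' fail (missing structure, unresolvable selection, unset boundaries) are
#' reported with a note instead of aborting the remaining rows.
#'
#' @param config A study configuration list, e.g. from
#'   [read_study_config()], [serpin_study_config()] or
#'   [make_study_fixture()].
#' @param structures Named list of `fodm_structure` objects keyed by the
#'   config's `pdb_id` values.
#' @return An object of class `fodm_study`: a list with `results` (one row
#'   per analyzed unit/fragment: form, pdb_id, unit, mode, n, divergences,
#'   rd, k, note) and `bfactor` (per-domain correlation rows). `tidy()`
#'   returns the results table.
#' @export
run_study <- function(config, structures) {
  k_grid <- config_k_grid(config)
  cutoff <- config$cutoff %||% 9
  rows <- list(); cors <- list(); units <- list()

  add_row <- function(form, pdb_id, unit, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (inherits(res, "fodm_result")) {
      g <- glance(res)
      g$label <- NULL
      rows[[length(rows) + 1]] <<- dplyr::bind_cols(
        tibble::tibble(form = form, pdb_id = pdb_id, unit = unit), g,
        tibble::tibble(note = NA_character_))
      res
    } else {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        form = form, pdb_id = pdb_id, unit = unit, mode = NA_character_,
        n = NA_integer_, dkl_ot = NA_real_, dkl_or = NA_real_, rd = NA_real_,
        k = NA_real_, dkl_om = NA_real_, note = as.character(res))
      NULL
    }
  }
  chain_sel <- function(chains, name, role = "chain") {
    fodm_selection(name, paste0("chains=", paste(chains, collapse = ",")),
                   role = role)
  }

  for (f in config$forms) {
    s <- structures[[f$pdb_id]]
    if (is.null(s)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        form = f$form, pdb_id = f$pdb_id, unit = "all", mode = NA_character_,
        n = NA_integer_, dkl_ot = NA_real_, dkl_or = NA_real_, rd = NA_real_,
        k = NA_real_, dkl_om = NA_real_, note = "structure not supplied")
      next
    }
    serpin <- unlist(f$serpin_chains)
    protease <- unlist(f$protease_chains)

    complex_unit <- NULL
    if (length(protease) > 0) {
      complex_unit <- add_row(f$form, f$pdb_id, "complex",
        analyze_unit(s, chain_sel(c(serpin, protease), "complex", "complex"),
                     cutoff = cutoff, k_grid = k_grid))
      if (!is.null(complex_unit)) {
        add_row(f$form, f$pdb_id, "serpin (in complex)",
          analyze_fragment(complex_unit, chain_sel(serpin, "serpin"),
                           k_grid = k_grid))
        add_row(f$form, f$pdb_id, "protease (in complex)",
          analyze_fragment(complex_unit, chain_sel(protease, "protease"),
                           k_grid = k_grid))
      }
      add_row(f$form, f$pdb_id, "protease (individual)",
        analyze_unit(s, chain_sel(protease, "protease"),
                     cutoff = cutoff, k_grid = k_grid))
    }
    serpin_unit <- add_row(f$form, f$pdb_id, "serpin (individual)",
      analyze_unit(s, chain_sel(serpin, "serpin"),
                   cutoff = cutoff, k_grid = k_grid))

    domain_units <- list()
    for (dn in names(f$domains %||% list())) {
      rng <- f$domains[[dn]]
      if (is.null(rng)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          form = f$form, pdb_id = f$pdb_id, unit = paste0(dn, " (individual)"),
          mode = NA_character_, n = NA_integer_, dkl_ot = NA_real_,
          dkl_or = NA_real_, rd = NA_real_, k = NA_real_, dkl_om = NA_real_,
          note = "no residue ranges configured")
        next
      }
      sel <- fodm_selection(dn, rng, role = "domain")
      if (!is.null(serpin_unit)) {
        add_row(f$form, f$pdb_id, paste0(dn, " (in chain)"),
                analyze_fragment(serpin_unit, sel, k_grid = k_grid))
      }
      du <- add_row(f$form, f$pdb_id, paste0(dn, " (individual)"),
                    analyze_unit(s, sel, cutoff = cutoff, k_grid = k_grid))
      domain_units[[dn]] <- du
      if (!is.null(du)) {
        cr <- tryCatch(correlate_profiles(du), error = function(e) NULL)
        if (!is.null(cr)) {
          cors[[length(cors) + 1]] <- dplyr::bind_cols(
            tibble::tibble(form = f$form, pdb_id = f$pdb_id, domain = dn),
            cr[, c("n", "r_t", "r_o", "r_m")])
        }
      }
    }

    for (sh in f$sheets %||% list()) {
      parent <- domain_units[[sh$parent %||% ""]] %||% serpin_unit
      if (is.null(parent)) next
      add_row(f$form, f$pdb_id, sh$name,
              analyze_fragment(parent,
                               fodm_selection(sh$name, sh$ranges,
                                              role = "beta_sheet"),
                               k_grid = k_grid))
    }
    if (!is.null(f$rcl) && !is.null(serpin_unit)) {
      add_row(f$form, f$pdb_id, "RCL",
              analyze_fragment(serpin_unit,
                               fodm_selection("RCL", f$rcl, role = "rcl"),
                               k_grid = k_grid))
    }
  }

  out <- list(results = dplyr::bind_rows(rows),
              bfactor = if (length(cors)) dplyr::bind_rows(cors) else
                tibble::tibble(form = character(), pdb_id = character(),
                               domain = character(), n = integer(),
                               r_t = numeric(), r_o = numeric(),
                               r_m = numeric()),
              study = config$study %||% "study")
  class(out) <- "fodm_study"
  out
}

config_k_grid <- function(config) {
  kg <- config$k_grid %||% list()
  round(seq(0, kg$max %||% 10, by = kg$step %||% 0.1), 10)
}

#' @export
print.fodm_study <- function(x, ...) {
  cat("<fodm_study> ", x$study, ": ", nrow(x$results), " unit rows, ",
      nrow(x$bfactor), " correlation rows\n", sep = "")
  print(x$results, n = 20)
  invisible(x)
}

#' @rdname run_study
#' @param x An `fodm_study`.
#' @param ... Unused.
#' @method tidy fodm_study
#' @export
tidy.fodm_study <- function(x, ...) x$results

#' Read a study configuration from YAML
#'
#' The configuration lists, per structural form: the PDB ID, serpin and
#' protease chain groupings, domain residue ranges (D1/D2; `~` where the
#' user must supply boundaries, e.g. from CATH), the sheet selections with
#' their parent domain and any incorporated-strand variants, and the
#' surface-loop (RCL) range. Optional top-level keys set the interaction
#' `cutoff` and the K grid.
#'
#' @param path Path to a YAML study configuration.
#' @return The configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$forms), length(cfg$forms) >= 1)
  for (f in cfg$forms) {
    if (is.null(f$pdb_id) || is.null(f$serpin_chains)) {
      stop("each form needs at least 'pdb_id' and 'serpin_chains'")
    }
  }
  cfg
}

#' The packaged serpin study configuration
#'
#' The five crystallographic forms of the serpin inhibition cycle (native
#' 1QLP, latent 2ANT, Michaelis complex 1K9O, acyl-enzyme complex 1EZX,
#' cleaved 7API) with their beta-sheet strand ranges, incorporated-strand
#' variants and chain groupings. Domain boundaries are deliberately unset
#' (`~`): they come from an external domain classification and must be
#' filled in by the user. Edit a copy of the bundled YAML
#' (`system.file("extdata", "serpin_study.yaml", package = "fodm")`) to do
#' so.
#'
#' @return The configuration list.
#' @export
serpin_study_config <- function() {
  read_study_config(system.file("extdata", "serpin_study.yaml",
                                package = "fodm", mustWork = TRUE))
}
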