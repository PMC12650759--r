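#' Write per-residue profiles as tab-separated text
#'
#' The numeric twin of a profile figure: chain, residue number, residue
#' name, then the T, O, R (and M) columns.
#'
#' @param result An `fodm_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(result, path) {
  out <- tidy(result)
  keep <- intersect(c("chain", "resno", "ins", "resname", "t", "o", "r", "m"),
                    names(out))
  utils::write.table(as.data.frame(out[, keep]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a study report as tab-separated tables
#'
#' Emits `study_results.tsv` (one row per analyzed unit/fragment) and
#' `study_bfactor.tsv` (per-domain correlation coefficients). RD and the
#' divergences are printed with 3 decimals and K with 1, the conventional
#' reporting precision; every cell comes straight from a computed result
#' object, nothing is derived in the formatting layer.
#'
#' @param study An `fodm_study` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_study_tsv <- function(study, dir) {
  stopifnot(inherits(study, "fodm_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- study$results
  fmt <- function(x, d) ifelse(is.na(x), "", formatC(x, digits = d, format = "f"))
  res_out <- data.frame(
    form = res$form, pdb_id = res$pdb_id, unit = res$unit,
    mode = ifelse(is.na(res$mode), "", res$mode),
    n = ifelse(is.na(res$n), "", res$n),
    dkl_ot = fmt(res$dkl_ot, 3), dkl_or = fmt(res$dkl_or, 3),
    rd = fmt(res$rd, 3), k = fmt(res$k, 1), dkl_om = fmt(res$dkl_om, 3),
    note = ifelse(is.na(res$note), "", res$note))
  p1 <- file.path(dir, "study_results.tsv")
  utils::write.table(res_out, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  bf <- study$bfactor
  bf_out <- data.frame(form = bf$form, pdb_id = bf$pdb_id, domain = bf$domain,
                       n = bf$n, r_t = fmt(bf$r_t, 3), r_o = fmt(bf$r_o, 3),
                       r_m = fmt(bf$r_m, 3))
  p2 <- file.path(dir, "study_bfactor.tsv")
  utils::write.table(bf_out, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
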