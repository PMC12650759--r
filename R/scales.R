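#' Residue hydrophobicity scales
#'
#' Returns one of the bundled per-residue intrinsic hydrophobicity scales,
#' min-max rescaled so that the most hydrophobic residue maps to 1 and the
#' least hydrophobic to 0. The model only requires nonnegative intrinsic
#' values, so any scale can be used once rescaled; the choice is a declared
#' parameter of every analysis.
#'
#' @param name Scale name: `"kyte_doolittle"` (default), `"fauchere_pliska"`
#'   or `"eisenberg"`.
#' @return A tibble with columns `residue_name` (3-letter code), `raw`
#'   (published value) and `h` (min-max normalized value in \[0, 1\]).
#' @examples
#' fodm_scale()
#' fodm_scale("fauchere_pliska")
#' @export
fodm_scale <- function(name = c("kyte_doolittle", "fauchere_pliska", "eisenberg")) {
  name <- match.arg(name)
  raw <- .fodm_scales[[name]]
  normalize_scale(tibble::tibble(residue_name = names(raw), raw = unname(raw)), name)
}

#' Read a hydrophobicity scale from a two-column text file
#'
#' The file format is whitespace-separated: 3-letter residue code, value.
#' Lines starting with `#` are ignored. Values are min-max rescaled to
#' \[0, 1\] exactly as for the bundled scales.
#'
#' @param path Path to the scale file.
#' @return A tibble with columns `residue_name`, `raw`, `h`.
#' @export
fodm_scale_from_file <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("residue_name", "raw"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) < 2) stop("scale file must define at least two residues")
  normalize_scale(tibble::as_tibble(df), basename(path))
}

normalize_scale <- function(tbl, label) {
  rng <- range(tbl$raw)
  if (diff(rng) <= 0) stop("degenerate scale: all raw values equal")
  tbl$residue_name <- toupper(tbl$residue_name)
  if (anyDuplicated(tbl$residue_name)) stop("duplicated residue names in scale")
  tbl$h <- (tbl$raw - rng[1]) / diff(rng)
  attr(tbl, "scale_name") <- label
  class(tbl) <- c("fodm_scale", class(tbl))
  tbl
}

# Look up normalized hydrophobicity for residue names; unknown names are an
# error unless a numeric fallback (on the normalized [0,1] scale) is given.
scale_lookup <- function(scale, residue_names, fallback = NULL) {
  stopifnot(inherits(scale, "fodm_scale"))
  idx <- match(toupper(residue_names), scale$residue_name)
  if (anyNA(idx)) {
    unknown <- unique(residue_names[is.na(idx)])
    if (is.null(fallback)) {
      stop("residue name(s) absent from hydrophobicity scale: ",
           paste(unknown, collapse = ", "))
    }
    stopifnot(is.numeric(fallback), fallback >= 0)
  }
  h <- scale$h[idx]
  if (!is.null(fallback)) h[is.na(h)] <- fallback
  h
}

# Published values; kept as named vectors so the tables read like the sources.
.fodm_scales <- list(
  kyte_doolittle = c(
    ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
    MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
    TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
    GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5),
  fauchere_pliska = c(
    ALA = 0.31, ARG = -1.01, ASN = -0.60, ASP = -0.77, CYS = 1.54,
    GLN = -0.22, GLU = -0.64, GLY = 0.00, HIS = 0.13, ILE = 1.80,
    LEU = 1.70, LYS = -0.99, MET = 1.23, PHE = 1.79, PRO = 0.72,
    SER = -0.04, THR = 0.26, TRP = 2.25, TYR = 0.96, VAL = 1.22),
  eisenberg = c(
    ALA = 0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90, CYS = 0.29,
    GLN = -0.85, GLU = -0.74, GLY = 0.48, HIS = -0.40, ILE = 1.38,
    LEU = 1.06, LYS = -1.50, MET = 0.64, PHE = 1.19, PRO = 0.12,
    SER = -0.18, THR = -0.05, TRP = 0.81, TYR = 0.26, VAL = 1.08)
)
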