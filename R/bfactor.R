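#' Pearson correlation with explicit degeneracy checks
#'
#' Thin wrapper over `stats::cor()` that enforces the preconditions used
#' throughout the B-factor analysis: equal length, at least 3 points,
#' nonzero variance on both sides.
#'
#' @param x,y Numeric vectors.
#' @return The product-moment correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Correlate T, O and M profiles with residue mobility
#'
#' Computes the Pearson correlation of each profile with the per-residue
#' mean B-factors. In a structure organized around a hydrophobic core, high
#' theoretical hydrophobicity marks buried, immobile positions, so these
#' correlations are typically negative. Because M is an affine map of T with
#' positive slope whenever `K < N*Tmax - 1`, `r_M` equals `r_T` exactly in
#' that regime; the function verifies this identity when it detects the
#' affine relation.
#'
#' @param result An `fodm_result` from [analyze_unit()] (its residue table
#'   supplies the B-factors), or pass profiles explicitly via `t`, `o`, `m`,
#'   `b`.
#' @param t,o,m,b Optional explicit vectors overriding `result`.
#' @return A one-row tibble: `label`, `n`, `r_t`, `r_o`, `r_m`.
#' @export
correlate_profiles <- function(result = NULL, t = NULL, o = NULL, m = NULL,
                               b = NULL) {
  if (!is.null(result)) {
    stopifnot(inherits(result, "fodm_result"))
    t <- t %||% result$profiles$t
    o <- o %||% result$profiles$o
    m <- m %||% result$profiles$m
    b <- b %||% result$residues$b
  }
  r_t <- pearson(t, b); r_o <- pearson(o, b); r_m <- pearson(m, b)
  # verify the affine identity r_M == r_T when M = a + c*T with c > 0
  fit <- stats::coef(stats::lm.fit(cbind(1, t), m))
  if (fit[2] > 0 && max(abs(m - (fit[1] + fit[2] * t))) < 1e-12) {
    stopifnot(abs(r_t - r_m) < 1e-12)
  }
  tibble::tibble(label = if (!is.null(result)) result$label else NA_character_,
                 n = length(t), r_t = r_t, r_o = r_o, r_m = r_m)
}

#' Stepwise elimination of outlying residues from a profile/B-factor relation
#'
#' Repeatedly fits an ordinary least-squares line `b ~ t`, removes the single
#' point with the largest absolute residual, and recomputes the correlation,
#' stopping once the correlation reaches the target magnitude with the sign
#' of the initial correlation, or once `max_fraction` of the points have
#' been removed (returned with `converged = FALSE`).
#'
#' @param t Profile values (typically T).
#' @param b Per-residue mean B-factors.
#' @param target_abs_r Target correlation magnitude in (0, 1); default 0.7.
#' @param max_fraction Maximum fraction of points to remove; default 0.2.
#' @return A list: `removed` (original indices in removal order), `r_initial`,
#'   `r_final`, `converged`, and `trace` (tibble with step, removed index,
#'   residual, correlation after removal).
#' @export
stepwise_outlier_elimination <- function(t, b, target_abs_r = 0.7,
                                         max_fraction = 0.2) {
  stopifnot(target_abs_r > 0, target_abs_r < 1,
            max_fraction > 0, max_fraction <= 1,
            length(t) == length(b))
  n <- length(t)
  max_remove <- floor(max_fraction * n)
  r0 <- pearson(t, b)
  sgn <- sign(r0)
  reached <- function(r) sign(r) == sgn && abs(r) >= target_abs_r
  keep <- seq_len(n)
  removed <- integer(0)
  trace <- list()
  r <- r0
  while (!reached(r) && length(removed) < max_remove) {
    if (length(keep) <= 4) stop("fewer than 4 points would remain")
    tt <- t[keep]; bb <- b[keep]
    beta <- stats::cov(tt, bb) / stats::var(tt)
    resid <- bb - (mean(bb) - beta * mean(tt)) - beta * tt
    worst <- which.max(abs(resid))
    removed <- c(removed, keep[worst])
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(removed), index = keep[worst],
      residual = resid[worst])
    keep <- keep[-worst]
    r <- pearson(t[keep], b[keep])
    trace[[length(trace)]]$r_after <- r
  }
  list(removed = removed, r_initial = r0, r_final = r,
       converged = reached(r),
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), index = integer(),
                        residual = numeric(), r_after = numeric()))
}

#' RD before and after removing outlying residues
#'
#' Recomputes RD on the complement of the removed set using fragment-style
#' renormalization of the unit's T and O profiles; the envelope is not
#' re-fitted.
#'
#' @param result An `fodm_result` for the full unit.
#' @param removed Integer indices (within the unit) of removed residues.
#' @param k_grid K search grid for the recomputation.
#' @return A list: `rd_before`, `rd_after`, and `result_after` (the
#'   fragment-mode `fodm_result` on the retained residues).
#' @export
rd_after_removal <- function(result, removed, k_grid = (0:100) / 10) {
  stopifnot(inherits(result, "fodm_result"))
  n <- result$n
  removed <- unique(as.integer(removed))
  stopifnot(all(removed >= 1 & removed <= n) | length(removed) == 0)
  if (length(removed) >= n) stop("all residues removed")
  keep <- setdiff(seq_len(n), removed)
  after <- fragment_result(result$profiles$t, result$profiles$o, keep,
                           k_grid = k_grid,
                           label = paste0(result$label %||% "unit", " (trimmed)"))
  if (!is.null(result$residues)) after$residues <- result$residues[keep, , drop = FALSE]
  list(rd_before = result$rd, rd_after = after$rd, result_after = after)
}
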