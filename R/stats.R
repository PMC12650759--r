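#' Kullback-Leibler divergence in bits
#'
#' `D_KL(p | q) = sum_i p_i log2(p_i / q_i)` with the convention
#' `0 * log 0 = 0`. A zero in `q` where `p` is positive is a structural
#' error, not clamped: the model's reference profiles (T, R, M) are strictly
#' positive by construction, so this can only arise from user-supplied
#' profiles.
#'
#' @param p,q Aligned unit-sum nonnegative numeric vectors.
#' @return Divergence in bits; nonnegative, 0 iff `p == q`.
#' @examples
#' kl_divergence(c(0.75, 0.25), c(0.5, 0.5))   # ~0.18872 bits
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("profile length mismatch")
  pos <- p > 0
  if (any(q[pos] <= 0)) stop("q has zero mass where p is positive")
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' The relative-distance statistic RD
#'
#' `RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))`, in \[0, 1\]. RD < 0.5 means
#' the observed distribution is closer to the idealized centric-nucleus
#' distribution T than to the flat distribution R, and is read as the
#' presence of a hydrophobic core; RD > 0.5 as its absence. The degenerate
#' case O = T = R (both divergences zero) is defined as RD = 0.
#'
#' @param o Observed profile.
#' @param t Theoretical profile.
#' @param r Reference profile; defaults to uniform over the common length.
#' @return RD in \[0, 1\].
#' @export
rd_statistic <- function(o, t, r = uniform_profile(length(o))) {
  d_ot <- kl_divergence(o, t)
  d_or <- kl_divergence(o, r)
  if (d_ot + d_or == 0) return(0)
  d_ot / (d_ot + d_or)
}

#' Environment-modified target profile M
#'
#' Blends the aqueous target T with its complement: the modified target is
#' `M = normalize(T + k * normalize(Tmax - T))`, where `Tmax = max(T)`. At
#' `k = 0`, `M = T` (pure aqueous ordering); as `k` grows, M approaches the
#' normalized complement `Tmax - T`, the membrane-like distribution with
#' hydrophobicity exposed at the surface and depleted at the centre.
#'
#' If T is exactly uniform the modification direction is undefined; M is
#' then defined as T and flagged with `attr(, "degenerate")`.
#'
#' @param t Unit-sum theoretical profile.
#' @param k Modification magnitude, >= 0.
#' @return Unit-sum numeric vector of the same length as `t`.
#' @export
modified_profile <- function(t, k) {
  stopifnot(k >= 0)
  tmax <- max(t)
  comp <- tmax - t
  s <- sum(comp)
  if (s <= 0) {                          # uniform T: Tmax - T == 0 everywhere
    out <- t
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  m <- t + k * comp / s
  m / sum(m)
}

#' Fit the environmental modification magnitude K
#'
#' Exhaustive search over a K grid for the value minimizing
#' `D_KL(O | M(K))`; ties resolve to the smaller K. The default grid 0 to 10
#' in steps of 0.1 matches the one-decimal precision K is conventionally
#' reported at. Because 0 is on the grid, the minimized divergence never
#' exceeds `D_KL(O | T)`.
#'
#' @param o Observed profile.
#' @param t Theoretical profile.
#' @param k_grid Candidate K values; default `seq(0, 10, by = 0.1)`.
#' @return A list with `k` (the minimizing grid value) and `dkl_om` (bits).
#' @export
fit_k <- function(o, t, k_grid = (0:100) / 10) {
  if (length(k_grid) == 0) stop("empty K grid")
  tmax <- max(t)
  comp <- tmax - t
  s <- sum(comp)
  if (s <= 0) return(list(k = k_grid[1], dkl_om = kl_divergence(o, t)))
  dn <- comp / s
  # rows: grid points; M(k) = (t + k*dn) / (1 + k) since sum(t)=1, sum(dn)=1
  pos <- o > 0
  dkl <- vapply(k_grid, function(k) {
    m <- (t + k * dn) / (1 + k)
    if (any(m[pos] <= 0)) return(Inf)
    sum(o[pos] * log2(o[pos] / m[pos]))
  }, numeric(1))
  i <- which.min(dkl)                    # which.min takes the first minimum
  list(k = k_grid[i], dkl_om = dkl[i])
}

#' Full divergence summary for one unit or fragment
#'
#' Bundles `D_KL(O|T)`, `D_KL(O|R)`, RD, the fitted K and `D_KL(O|M(K))`
#' into an `fodm_result`.
#'
#' @param t,o Aligned unit-sum profiles.
#' @param k_grid K search grid, as in [fit_k()].
#' @param mode `"unit"` or `"fragment"`.
#' @param label Unit/fragment label carried into reports.
#' @return An `fodm_result` (see [tidy.fodm_result()] and
#'   [glance.fodm_result()]).
#' @export
fodm_result <- function(t, o, k_grid = (0:100) / 10,
                        mode = c("unit", "fragment"), label = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(t) == length(o))
  r <- uniform_profile(length(t))
  fit <- fit_k(o, t, k_grid)
  res <- list(
    label = label, mode = mode, n = length(t),
    dkl_ot = kl_divergence(o, t),
    dkl_or = kl_divergence(o, r),
    rd = rd_statistic(o, t, r),
    k = fit$k, dkl_om = fit$dkl_om,
    profiles = tibble::tibble(t = t, o = o, r = r,
                              m = as.numeric(modified_profile(t, fit$k)))
  )
  class(res) <- "fodm_result"
  res
}

#' Fragment-mode result: renormalized sub-profiles of an enclosing unit
#'
#' Restricts the unit's T and O profiles to the fragment's positions and
#' renormalizes each to unit sum; R is rebuilt as uniform over the fragment
#' length; K is re-fitted on the renormalized sub-profiles (Tmax recomputed
#' within the fragment). No new envelope is fitted: the fragment is judged
#' by its contribution to the enclosing unit's distribution.
#'
#' @param t,o The enclosing unit's profiles.
#' @param indices Positions (integer or logical) of the fragment within the
#'   unit.
#' @param k_grid K search grid.
#' @param label Fragment label.
#' @return An `fodm_result` with `mode = "fragment"`.
#' @export
fragment_result <- function(t, o, indices, k_grid = (0:100) / 10,
                            label = NA_character_) {
  if (is.logical(indices)) indices <- which(indices)
  if (length(indices) == 0) stop("empty fragment")
  stopifnot(all(indices >= 1), all(indices <= length(t)))
  t_sub <- t[indices]; o_sub <- o[indices]
  if (sum(t_sub) <= 0 || sum(o_sub) <= 0) stop("fragment sub-profile sums to zero")
  fodm_result(t_sub / sum(t_sub), o_sub / sum(o_sub),
              k_grid = k_grid, mode = "fragment", label = label)
}

#' @export
print.fodm_result <- function(x, ...) {
  cat("<fodm_result> ", if (is.na(x$label)) "" else paste0(x$label, " "),
      "[", x$mode, " mode, n = ", x$n, "]\n", sep = "")
  cat(sprintf("  DKL(O|T) = %.3f  DKL(O|R) = %.3f  RD = %.3f  K = %.1f  DKL(O|M) = %.3f\n",
              x$dkl_ot, x$dkl_or, x$rd, x$k, x$dkl_om))
  invisible(x)
}

#' Per-residue profile table of a result
#'
#' @param x An `fodm_result`.
#' @param ... Unused.
#' @return A tibble with one row per residue: identity columns when the
#'   result came from [analyze_unit()], plus `t`, `o`, `r`, `m`.
#' @method tidy fodm_result
#' @export
tidy.fodm_result <- function(x, ...) {
  out <- x$profiles
  if (!is.null(x$residues)) out <- dplyr::bind_cols(x$residues, out)
  out
}

#' One-row summary of a result
#'
#' @param x An `fodm_result`.
#' @param ... Unused.
#' @return A one-row tibble: `label`, `mode`, `n`, `dkl_ot`, `dkl_or`, `rd`,
#'   `k`, `dkl_om`.
#' @method glance fodm_result
#' @export
glance.fodm_result <- function(x, ...) {
  tibble::tibble(label = x$label, mode = x$mode, n = x$n,
                 dkl_ot = x$dkl_ot, dkl_or = x$dkl_or, rd = x$rd,
                 k = x$k, dkl_om = x$dkl_om)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
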