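#' Fit the encapsulating 3D Gaussian envelope of a structural unit
#'
#' Translates the unit's effective atoms to their geometric centre, rotates
#' them onto the principal axes of the point cloud (ordered by decreasing
#' variance) and sets each axis sigma by the three-sigma rule,
#' `sigma_axis = max_i |coordinate_i| / 3`, so the whole unit lies inside
#' three standard deviations of the fitted Gaussian. Axis signs are
#' canonicalized so the most extreme coordinate along each axis is positive,
#' which removes the reflection ambiguity of principal axes.
#'
#' @param structure An `fodm_structure` with at least 2 residues.
#' @return An object of class `fodm_envelope`: a list with `center`
#'   (original-frame 3-vector), `rotation` (3x3 orthonormal, input frame to
#'   canonical frame), `sigmas` (length-3, A) and `canonical` (N x 3 matrix
#'   of canonicalized effective-atom coordinates, zero mean per axis).
#' @export
fit_envelope <- function(structure) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) stop("envelope fitting needs at least 2 residues")
  center <- colMeans(xyz)
  cc <- sweep(xyz, 2, center)
  # principal axes of the centred cloud; identity fallback for degenerate
  # covariance (e.g. n == 2 exactly along one axis still works via eigen)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
  rot <- ev$vectors                      # columns ordered by decreasing variance
  can <- cc %*% rot
  # sign canonicalization: the coordinate of largest magnitude on each axis
  # is made positive
  flip <- vapply(1:3, function(a) {
    i <- which.max(abs(can[, a]))
    if (can[i, a] < 0) -1 else 1
  }, numeric(1))
  rot <- rot %*% diag(flip)
  can <- cc %*% rot
  sigmas <- apply(abs(can), 2, max) / 3
  if (any(sigmas <= 0)) {
    stop("degenerate geometry: zero extent along ", sum(sigmas <= 0),
         " principal axis/axes (collinear or coincident effective atoms)")
  }
  structure(list(center = center, rotation = rot, sigmas = sigmas,
                 canonical = can),
            class = "fodm_envelope")
}

#' @export
print.fodm_envelope <- function(x, ...) {
  cat("<fodm_envelope> sigmas (A):",
      paste(sprintf("%.3f", x$sigmas), collapse = ", "),
      " n =", nrow(x$canonical), "\n")
  invisible(x)
}

#' Theoretical hydrophobicity profile T from the fitted Gaussian
#'
#' Evaluates the product of the three axis-wise Gaussians at every
#' canonicalized effective-atom position and normalizes to unit sum. T is
#' the idealized distribution of a centric hydrophobic nucleus with a polar
#' surface: maximal at the centre, decaying outwards.
#'
#' @param structure An `fodm_structure` (used when `envelope` is omitted).
#' @param envelope An [fit_envelope()] result; fitted from `structure` if
#'   missing.
#' @return Numeric vector of length N summing to 1.
#' @export
theoretical_profile <- function(structure, envelope = fit_envelope(structure)) {
  can <- envelope$canonical
  if (!all(is.finite(can))) stop("non-finite coordinates")
  s <- envelope$sigmas
  stopifnot(all(s > 0))
  raw <- exp(-can[, 1]^2 / (2 * s[1]^2)) *
         exp(-can[, 2]^2 / (2 * s[2]^2)) *
         exp(-can[, 3]^2 / (2 * s[3]^2))
  raw / sum(raw)
}

#' Observed hydrophobicity profile O from pairwise Levitt interactions
#'
#' Aggregates, for every residue, the hydrophobic interaction collected from
#' all neighbours within the cutoff: each ordered pair (i, j) contributes
#' `(h_i + h_j) * w(r_ij)` where `w` is Levitt's sigmoid distance weight,
#' equal to 1 at contact and falling smoothly to 0 at `r = cutoff`. The raw
#' per-residue sums are normalized to a unit-sum distribution.
#'
#' @param structure An `fodm_structure` with >= 2 residues and nonnegative
#'   intrinsic hydrophobicities.
#' @param cutoff Interaction cutoff c in Angstrom; default 9.
#' @param include_self Include the j = i term? Default `FALSE` (O reflects
#'   inter-residue interactions only).
#' @return Numeric vector of length N summing to 1.
#' @export
observed_profile <- function(structure, cutoff = 9, include_self = FALSE) {
  n <- nrow(structure)
  if (n < 2) stop("observed profile needs at least 2 residues")
  h <- structure$h
  stopifnot(all(h >= 0))
  d <- as.matrix(stats::dist(structure[, c("x", "y", "z")]))
  w <- levitt_weight(d, cutoff)
  if (!include_self) diag(w) <- 0 else diag(w) <- 1
  hh <- outer(h, h, "+")
  raw <- unname(rowSums(hh * w))
  total <- sum(raw)
  if (total <= 0) {
    stop("no observed hydrophobic interactions: all residue pairs beyond the ",
         cutoff, " A cutoff")
  }
  raw / total
}

#' Levitt distance weight
#'
#' The polynomial sigmoid `1 - 1/2 (7p^2 - 9p^4 + 5p^6 - p^8)` with
#' `p = r / cutoff`, equal to 1 at `r = 0`, strictly decreasing on
#' `(0, cutoff)` and exactly 0 from the cutoff outwards.
#'
#' @param r Distances (any numeric array), Angstrom.
#' @param cutoff Cutoff distance c, Angstrom; default 9.
#' @return Weights in \[0, 1\], same shape as `r`.
#' @export
levitt_weight <- function(r, cutoff = 9) {
  p2 <- (r / cutoff)^2
  w <- 1 - 0.5 * (7 * p2 - 9 * p2^2 + 5 * p2^3 - p2^4)
  w[r > cutoff] <- 0
  w
}

#' Uniform reference profile R
#'
#' The distribution with no hydrophobic differentiation: every residue
#' carries 1/N.
#'
#' @param n Number of residues (>= 1).
#' @return Numeric vector of length `n`, all entries `1/n`.
#' @export
uniform_profile <- function(n) {
  stopifnot(n >= 1)
  rep(1 / n, n)
}

#' Compute the T, O and R profiles of a unit as a tibble
#'
#' Convenience wrapper running [fit_envelope()], [theoretical_profile()],
#' [observed_profile()] and [uniform_profile()] over one structural unit.
#'
#' @inheritParams observed_profile
#' @return A tibble with the residue identity columns and `t`, `o`, `r`
#'   profile columns; the fitted envelope in `attr(, "envelope")`.
#' @export
fodm_profiles <- function(structure, cutoff = 9, include_self = FALSE) {
  env <- fit_envelope(structure)
  out <- tibble::as_tibble(structure[, c("chain", "resno", "ins", "resname", "h", "b")])
  out$t <- theoretical_profile(structure, env)
  out$o <- observed_profile(structure, cutoff = cutoff, include_self = include_self)
  out$r <- uniform_profile(nrow(out))
  attr(out, "envelope") <- env
  out
}
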