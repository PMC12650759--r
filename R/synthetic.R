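#' Generate a synthetic residue-level structure
#'
#' Samples effective-atom positions from an anisotropic Gaussian cloud with
#' a minimum inter-residue spacing (rejection sampling, so no two effective
#' atoms fall inside each other's contact range degenerately), then assigns
#' residue identities by rank-matching intrinsic hydrophobicity to the
#' distance from the cloud centre:
#'
#' * `micellar` — most hydrophobic residues nearest the centre (hydrophobic
#'   core, polar surface; the organization the T distribution idealizes);
#' * `inverted` — most hydrophobic residues at the surface;
#' * `uniform` — a single residue type everywhere (no differentiation);
#' * `two_blob_complex` — two micellar clouds of unequal size offset along
#'   the long axis, tagged as chains A and B: an asymmetric "complex" whose
#'   whole-assembly organization is worse than either chain's own.
#'
#' B-factors follow `b0 + b1 * radial_distance + N(0, sigma_b)`, truncated
#' at zero — the mobility gradient from buried to surface residues.
#'
#' @param n Number of residues (>= 10).
#' @param organization One of `"micellar"`, `"inverted"`, `"uniform"`,
#'   `"two_blob_complex"`.
#' @param sigmas Cloud standard deviations per axis, Angstrom.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param b0,b1,sigma_b B-factor rule parameters (A^2, A^2 per A, A^2).
#' @param min_dist Minimum pairwise effective-atom distance, Angstrom.
#' @param scale Hydrophobicity scale supplying residue identities.
#' @return An `fodm_structure` tibble.
#' @export
make_structure <- function(n, organization = c("micellar", "inverted",
                                               "uniform", "two_blob_complex"),
                           sigmas = c(15, 12, 9), seed = 1,
                           b0 = 20, b1 = 1.5, sigma_b = 2,
                           min_dist = 3.5, scale = fodm_scale()) {
  organization <- match.arg(organization)
  stopifnot(n >= 10, length(sigmas) == 3, all(sigmas > 0))
  withr::with_seed(seed, {
    if (organization == "two_blob_complex") {
      n_a <- ceiling(0.65 * n); n_b <- n - n_a
      offset <- 3.2 * sigmas[1]
      a <- sample_cloud(n_a, sigmas, min_dist)
      b <- sample_cloud(n_b, sigmas * 0.6, min_dist)
      b[, 1] <- b[, 1] + offset
      xyz <- rbind(a, b)
      chain <- rep(c("A", "B"), c(n_a, n_b))
      # radial distance from each blob's own centre (drives H and B rules)
      radial <- c(sqrt(rowSums(sweep(a, 2, colMeans(a))^2)),
                  sqrt(rowSums(sweep(b, 2, colMeans(b))^2)))
      grp <- chain
    } else {
      xyz <- sample_cloud(n, sigmas, min_dist)
      chain <- rep("A", n)
      radial <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
      grp <- rep("A", n)
    }
    resname <- character(n)
    if (organization == "uniform") {
      resname[] <- "LEU"
    } else {
      decreasing <- organization != "inverted"   # micellar blobs in complexes too
      for (g in unique(grp)) {
        i <- which(grp == g)
        drawn <- sample(scale$residue_name, length(i), replace = TRUE)
        drawn <- drawn[order(scale_lookup(scale, drawn),
                             decreasing = decreasing)]
        resname[i[order(radial[i])]] <- drawn
      }
    }
    b_fac <- pmax(0, b0 + b1 * radial + stats::rnorm(n, 0, sigma_b))
    res <- tibble::tibble(
      chain = chain,
      resno = stats::ave(seq_len(n), chain, FUN = seq_along),
      ins = "", resname = resname,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      h = scale_lookup(scale, resname), b = b_fac)
    new_structure(res, source_label = paste0("synthetic_", organization),
                  scale_name = attr(scale, "scale_name"))
  })
}

# Gaussian cloud with minimum pairwise spacing via rejection sampling.
sample_cloud <- function(n, sigmas, min_dist, max_tries = 200 * n) {
  pts <- matrix(NA_real_, n, 3)
  k <- 0; tries <- 0
  while (k < n) {
    tries <- tries + 1
    if (tries > max_tries) stop("cannot place ", n, " points at spacing ",
                                min_dist, " A inside the cloud; enlarge sigmas")
    cand <- stats::rnorm(3) * sigmas
    if (k == 0 ||
        min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - cand)^2))) >= min_dist) {
      k <- k + 1
      pts[k, ] <- cand
    }
  }
  pts
}

#' Generate a (T, O) profile pair with known modification magnitude
#'
#' Builds T from a random envelope over a random point cloud and constructs
#' O exactly as `modified_profile(T, k_true)`, optionally perturbed by
#' multiplicative noise and renormalized — the parameter-recovery harness
#' for [fit_k()].
#'
#' @param n Number of positions.
#' @param k_true True modification magnitude (a grid value).
#' @param noise Multiplicative noise half-width (e.g. 0.01 for 1 percent);
#'   0 for an exact construction.
#' @param seed Integer seed.
#' @return A list with unit-sum vectors `t` and `o` and the generating
#'   `k_true`.
#' @export
make_profile_pair <- function(n = 50, k_true = 0, noise = 0, seed = 1) {
  stopifnot(n >= 3, k_true >= 0, noise >= 0)
  withr::with_seed(seed, {
    xyz <- matrix(stats::rnorm(3 * n), ncol = 3) %*% diag(c(12, 9, 6))
    str <- new_structure(tibble::tibble(
      chain = "A", resno = seq_len(n), ins = "", resname = "ALA",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], h = 1, b = 0))
    t <- theoretical_profile(str)
    o <- as.numeric(modified_profile(t, k_true))
    if (noise > 0) {
      o <- o * (1 + stats::runif(n, -noise, noise))
      o <- o / sum(o)
    }
    list(t = t, o = o, k_true = k_true)
  })
}

#' Generate a miniature end-to-end study fixture
#'
#' Five synthetic "conformational forms" mirroring the layout of a serpin
#' study: three single-chain micellar forms and two asymmetric two-chain
#' "complexes", each with two "domains", a "sheet" per domain (with an
#' incorporated-strand variant), and a surface-loop selection, plus the
#' study configuration that drives [run_study()] over them.
#'
#' @param seed Integer seed.
#' @param n Residues per serpin-like chain.
#' @return A list with `structures` (named list of `fodm_structure`) and
#'   `config` (a study configuration list).
#' @export
make_study_fixture <- function(seed = 1, n = 80) {
  stopifnot(n >= 40)
  forms <- list(
    list(form = "NATIVE",    pdb_id = "SYN1", complex = FALSE),
    list(form = "LATENT",    pdb_id = "SYN2", complex = FALSE),
    list(form = "MICHAELIS", pdb_id = "SYN3", complex = TRUE),
    list(form = "COVALENT",  pdb_id = "SYN4", complex = TRUE),
    list(form = "CLEAVED",   pdb_id = "SYN5", complex = FALSE)
  )
  structures <- list()
  cfg_forms <- list()
  half <- floor(n / 2)
  for (i in seq_along(forms)) {
    f <- forms[[i]]
    if (f$complex) {
      s <- make_structure(round(n / 0.65), "two_blob_complex", seed = seed + i)
      serpin <- "A"; protease <- "B"
    } else {
      s <- make_structure(n, "micellar", seed = seed + i)
      serpin <- "A"; protease <- character(0)
    }
    n_a <- sum(s$chain == "A")
    h2 <- floor(n_a / 2)
    structures[[f$pdb_id]] <- s
    cfg_forms[[i]] <- list(
      form = f$form, pdb_id = f$pdb_id,
      serpin_chains = list(serpin),
      protease_chains = as.list(protease),
      domains = list(D1 = sprintf("A:1-%d", h2),
                     D2 = sprintf("A:%d-%d", h2 + 1, n_a)),
      sheets = list(
        list(name = "sheet_A", parent = "D1",
             ranges = sprintf("A:3-%d,A:%d-%d", floor(h2 / 3),
                              floor(h2 / 3) + 4, floor(2 * h2 / 3))),
        list(name = "sheet_A_incorp", parent = "D1",
             ranges = sprintf("A:3-%d,A:%d-%d,A:%d-%d", floor(h2 / 3),
                              floor(h2 / 3) + 4, floor(2 * h2 / 3),
                              floor(2 * h2 / 3) + 2, h2 - 2)),
        list(name = "sheet_B", parent = "D2",
             ranges = sprintf("A:%d-%d", h2 + 3, h2 + 3 + floor(h2 / 2)))),
      rcl = sprintf("A:%d-%d", n_a - 7, n_a))
  }
  list(structures = structures,
       config = list(study = "synthetic_fixture", cutoff = 9,
                     k_grid = list(max = 10, step = 0.1),
                     forms = cfg_forms))
}
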