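# Shared fixtures and independent oracles for the test suite.

# Brute-force double-loop evaluation of the observed-profile aggregation:
# the independent oracle for observed_profile(), written from the pairwise
# definition with no shared code.
brute_force_observed <- function(structure, cutoff = 9) {
  n <- nrow(structure)
  h <- structure$h
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  raw <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= cutoff) {
        p <- r / cutoff
        w <- 1 - 0.5 * (7 * p^2 - 9 * p^4 + 5 * p^6 - p^8)
        acc <- acc + (h[i] + h[j]) * w
      }
    }
    raw[i] <- acc
  }
  raw / sum(raw)
}

# Random unit-sum strictly positive profile.
random_profile <- function(n) {
  x <- stats::runif(n, min = 0.01)
  x / sum(x)
}

# Apply a random proper rotation + translation to a structure's coordinates.
rigid_transform <- function(structure) {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% rot
  shift <- stats::rnorm(3, sd = 20)
  structure$x <- xyz[, 1] + shift[1]
  structure$y <- xyz[, 2] + shift[2]
  structure$z <- xyz[, 3] + shift[3]
  structure
}

# Minimal hand-written PDB text covering the parsing corner cases.
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.000   0.000   0.000  1.00 30.00           C",
    "ATOM      3  CA  GLY A   2       1.000   2.000   3.000  1.00 20.00           C",
    "ATOM      4  HA  GLY A   2       1.500   2.000   3.000  1.00 99.00           H",
    "ATOM      5  CA ALEU A   3       4.000   4.000   4.000  0.60 15.00           C",
    "ATOM      6  CA BLEU A   3       6.000   6.000   6.000  0.40 25.00           C",
    "ATOM      7  CA  VAL B  10       8.000   0.000   0.000  1.00 12.00           C",
    "HETATM    8  O   HOH A 101       9.000   9.000   9.000  1.00 50.00           O",
    "END")
  writeLines(lines, path)
  path
}

# A small structure with author numbering laid out like a serpin chain, for
# selection arithmetic against published-style residue ranges.
numbered_structure <- function(resno, chain = "A", seed = 1) {
  n <- length(resno)
  s <- make_structure(n, "micellar", seed = seed)
  s$resno <- resno
  s$chain <- chain
  s
}
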