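test_that("pearson matches hand values and rejects degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -2 * x + 5), -1)
  expect_equal(pearson(x, c(1, 3, 2)), 0.5)
  expect_error(pearson(x, c(1, 2)), "length")
  expect_error(pearson(c(1, 1, 1), x), "variance")
  expect_error(pearson(c(1, 2), c(3, 4)), "3 points")
})

test_that("profile-mobility correlations behave like a buried-core gradient", {
  s <- make_structure(100, "micellar", seed = 41, b1 = 1.5, sigma_b = 2)
  u <- analyze_unit(s)
  cr <- correlate_profiles(u)
  # B grows with radial distance while T decays from the centre
  expect_lt(cr$r_t, 0)
  # M at the fitted K is an affine image of T with positive slope
  expect_equal(cr$r_t, cr$r_m, tolerance = 1e-12)
})

test_that("correlations of M(K) and T with B coincide exactly under positive slope", {
  withr::with_seed(42, {
    for (i in 1:10) {
      t <- random_profile(40)
      b <- runif(40, 10, 60)
      k <- sample(seq(0, 2, by = 0.1), 1)
      m <- as.numeric(modified_profile(t, k))
      slope <- 1 - k / (40 * max(t) - 1)
      if (slope > 0) {
        expect_equal(pearson(m, b), pearson(t, b), tolerance = 1e-12)
      }
    }
  })
})

test_that("shuffled B-factors show no correlation on average", {
  withr::with_seed(43, {
    s <- make_structure(80, "micellar", seed = 44)
    t <- theoretical_profile(s)
    r <- replicate(1000, pearson(t, sample(s$b)))
    se <- sd(r) / sqrt(1000)
    expect_lt(abs(mean(r)), 3 * se + 1e-3)
  })
})

test_that("correlations are invariant to affine rescaling of B-factors", {
  s <- make_structure(50, "micellar", seed = 45)
  u <- analyze_unit(s)
  a <- correlate_profiles(u)
  b <- correlate_profiles(u, b = 3 * u$residues$b + 7)
  expect_equal(a[, c("r_t", "r_o", "r_m")], b[, c("r_t", "r_o", "r_m")],
               tolerance = 1e-12)
})

test_that("stepwise elimination removes a planted outlier first and stops", {
  withr::with_seed(46, {
    n <- 30
    t <- seq(0.01, 0.06, length.out = n)
    b <- 60 - 600 * t + rnorm(n, 0, 1)        # strong negative relation
    stopifnot(pearson(t, b) < -0.9)
    b[15] <- b[15] + 60                        # one far outlier
    expect_gt(pearson(t, b), -0.7)             # it masks the relation
    el <- stepwise_outlier_elimination(t, b, target_abs_r = 0.7)
    expect_equal(el$removed[1], 15)
    expect_equal(length(el$removed), 1)
    expect_true(el$converged)
    expect_lte(el$r_final, -0.7)
    # perfectly linear data: no removals at all
    el0 <- stepwise_outlier_elimination(t, -2 * t + 1e-4 * rnorm(n, 0, 1e-6))
    expect_equal(length(el0$removed), 0)
  })
})

test_that("elimination is bounded, deterministic and flags non-convergence", {
  withr::with_seed(47, {
    n <- 50
    t <- random_profile(n)
    b <- runif(n, 10, 60)                      # unrelated mobility
    el <- stepwise_outlier_elimination(t, b, target_abs_r = 0.95,
                                       max_fraction = 0.2)
    expect_false(el$converged)
    expect_lte(length(el$removed), floor(0.2 * n))
    el2 <- stepwise_outlier_elimination(t, b, target_abs_r = 0.95,
                                        max_fraction = 0.2)
    expect_identical(el$removed, el2$removed)
  })
})

test_that("RD recomputation after removal matches the fragment oracle", {
  withr::with_seed(48, {
    # construction: O agrees with T everywhere except a few residues carrying
    # a planted hydrophobicity excess, so those residues account for all of
    # DKL(O|T) and their removal must lower RD
    t <- random_profile(80)
    excess <- c(7, 23, 41, 60, 72)
    o <- t
    o[excess] <- o[excess] + 0.03
    o <- o / sum(o)
    u <- fodm_result(t, o)
    # no removal: unchanged
    expect_equal(rd_after_removal(u, integer(0))$rd_after, u$rd)
    out <- rd_after_removal(u, excess)
    expect_lt(out$rd_after, out$rd_before)
    expect_equal(out$rd_after, 0, tolerance = 1e-9)   # sub-O is proportional to sub-T
    # oracle on an arbitrary removal set: renormalized complement from the definitions
    removed <- c(3, 15, 55)
    keep <- setdiff(seq_len(80), removed)
    ts <- t[keep] / sum(t[keep])
    os <- o[keep] / sum(o[keep])
    d_ot <- sum(os * log2(os / ts))
    d_or <- sum(os * log2(os * length(keep)))
    expect_equal(rd_after_removal(u, removed)$rd_after,
                 d_ot / (d_ot + d_or), tolerance = 1e-12)
    expect_error(rd_after_removal(u, 1:80), "all residues")
  })
})
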