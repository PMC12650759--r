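test_that("KL divergence matches closed forms and rejects bad input", {
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log2(1.5) + 0.25 * log2(0.5), tolerance = 1e-15)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  p <- random_profile(20)
  expect_equal(kl_divergence(p, p), 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)), "length")
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "zero mass")
  # 0 * log 0 convention: zero p-mass positions contribute nothing
  expect_equal(kl_divergence(c(0.5, 0.5, 0), rep(1 / 3, 3)),
               kl_divergence(c(0.5, 0.5), c(1 / 3, 1 / 3)))
})

test_that("RD hits its endpoints and the degenerate case is 0", {
  withr::with_seed(5, {
    t <- random_profile(30)
    r <- uniform_profile(30)
    expect_equal(rd_statistic(t, t, r), 0)
    expect_equal(rd_statistic(r, t, r), 1)
    expect_equal(rd_statistic(r, r, r), 0)      # O = T = R
  })
})

test_that("RD increases strictly along the mixture path from T to R", {
  withr::with_seed(6, {
    t <- random_profile(40)
    r <- uniform_profile(40)
    lambdas <- seq(0, 1, by = 0.05)
    rd <- vapply(lambdas, function(l) rd_statistic((1 - l) * t + l * r, t, r),
                 numeric(1))
    expect_true(all(diff(rd) > 0))
    expect_equal(rd[1], 0)
    expect_equal(rd[length(rd)], 1)
  })
})

test_that("the modified profile blends T toward its complement", {
  t <- c(0.5, 0.3, 0.2)
  expect_equal(modified_profile(t, 0), t)
  expect_equal(modified_profile(t, 1), c(0.25, 0.35, 0.40))
  # limiting form: the normalized complement Tmax - T
  comp <- (max(t) - t) / sum(max(t) - t)
  expect_lt(max(abs(modified_profile(t, 1e6) - comp)), 1e-5)
  # uniform T has no modification direction
  u <- uniform_profile(4)
  m <- modified_profile(u, 2)
  expect_equal(as.numeric(m), u)
  expect_true(isTRUE(attr(m, "degenerate")))
  expect_error(modified_profile(t, -1))
})

test_that("K is recovered exactly from noiseless constructions", {
  withr::with_seed(8, {
    t <- random_profile(30)
    o <- as.numeric(modified_profile(t, 0.8))
    fit <- fit_k(o, t)
    expect_identical(fit$k, 0.8)
    expect_lt(fit$dkl_om, 1e-12)
    expect_identical(fit_k(t, t)$k, 0)
    expect_equal(fit_k(t, t)$dkl_om, 0)
  })
  expect_error(fit_k(c(0.5, 0.5), c(0.5, 0.5), k_grid = numeric(0)), "empty")
})

test_that("K recovery tolerates 1 percent multiplicative noise", {
  hits <- 0
  for (seed in 1:100) {
    pp <- make_profile_pair(50, k_true = 2.3, noise = 0.01, seed = seed)
    k <- fit_k(pp$o, pp$t)$k
    if (k %in% c(2.2, 2.3, 2.4)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("the fitted divergence never exceeds DKL(O|T)", {
  withr::with_seed(9, {
    for (i in 1:20) {
      t <- random_profile(25)
      o <- random_profile(25)
      fit <- fit_k(o, t)
      expect_lte(fit$dkl_om, kl_divergence(o, t) + 1e-12)
      expect_true(fit$k %in% ((0:100) / 10))
    }
  })
})

test_that("fragment of the whole equals the unit result bit for bit", {
  withr::with_seed(10, {
    t <- random_profile(50)
    o <- random_profile(50)
    unit <- fodm_result(t, o)
    frag <- fragment_result(t, o, seq_len(50))
    expect_identical(frag$rd, unit$rd)
    expect_identical(frag$k, unit$k)
  })
})

test_that("fragment results equal a brute-force renormalized recomputation", {
  withr::with_seed(11, {
    t <- random_profile(50)
    o <- random_profile(50)
    idx <- sort(sample(50, 10))
    got <- fragment_result(t, o, idx)
    # oracle: renormalize by hand, compute each statistic from its definition
    ts <- t[idx] / sum(t[idx]); os <- o[idx] / sum(o[idx]); rs <- rep(1 / 10, 10)
    d_ot <- sum(os * log2(os / ts)); d_or <- sum(os * log2(os / rs))
    expect_equal(got$rd, d_ot / (d_ot + d_or), tolerance = 1e-12)
    ks <- (0:100) / 10
    dn <- (max(ts) - ts) / sum(max(ts) - ts)
    dkl <- sapply(ks, function(k) {
      m <- (ts + k * dn); m <- m / sum(m); sum(os * log2(os / m))
    })
    expect_equal(got$k, ks[which.min(dkl)])
    # a fragment whose O is proportional to its T is perfectly ordered
    o2 <- o; o2[idx] <- t[idx] * sum(o[idx]) / sum(t[idx])
    expect_equal(fragment_result(t, o2, idx)$rd, 0, tolerance = 1e-12)
  })
})
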