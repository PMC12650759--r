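test_that("unit analysis is deterministic and discriminates organization", {
  s <- make_structure(100, "micellar", seed = 21)
  u1 <- analyze_unit(s)
  u2 <- analyze_unit(s)
  expect_identical(glance(u1), glance(u2))
  expect_lt(u1$rd, 0.5)                       # hydrophobic core present
  inv <- analyze_unit(make_structure(100, "inverted", seed = 21))
  expect_gt(inv$rd, 0.5)                      # hydrophobic surface
  expect_error(analyze_unit(s[1:2, ]), "fewer than 3")
})

test_that("whole-unit fragments reproduce the unit statistics", {
  s <- make_structure(60, "micellar", seed = 22)
  u <- analyze_unit(s)
  f <- analyze_fragment(u, seq_len(60))
  expect_equal(f$rd, u$rd)
  expect_equal(f$k, u$k)
  expect_equal(f$mode, "fragment")
})

test_that("chain-in-complex and individual-chain modes disagree for asymmetric complexes", {
  s <- make_structure(120, "two_blob_complex", seed = 23)
  cx <- analyze_unit(s, label = "complex")
  in_complex <- analyze_fragment(cx, fodm_selection("A", "chains=A"))
  individual <- analyze_unit(s, fodm_selection("A", "chains=A"))
  expect_false(isTRUE(all.equal(in_complex$rd, individual$rd)))
  # the asymmetric assembly is less micelle-like than its parts
  expect_gt(cx$rd, individual$rd)
})

test_that("fragments outside the unit are rejected", {
  s <- make_structure(30, "micellar", seed = 24)
  u <- analyze_unit(s)
  expect_error(analyze_fragment(u, fodm_selection("far", "B:1-10")),
               "not contained")
})

test_that("status flags partition residues around the T-M band", {
  withr::with_seed(25, {
    t <- random_profile(20)
    res <- fodm_result(t, t)
    expect_true(all(annotate_status(res)$status == "conformant"))
    o <- t; o[7] <- t[7] + 0.1
    res2 <- fodm_result(t, o)
    res2$profiles$m <- t                       # K = 0 band: M coincides with T
    st <- annotate_status(res2)$status
    expect_equal(as.character(st[7]), "excess")
    expect_true(all(st[-7] == "conformant"))
    # random profiles: the three flags partition all residues
    res3 <- fodm_result(random_profile(40), random_profile(40))
    expect_equal(sum(table(annotate_status(res3)$status)), 40)
  })
})

test_that("run_study reports every configured unit and tolerates failures", {
  fx <- make_study_fixture(seed = 31)
  st <- run_study(fx$config, fx$structures)
  res <- tidy(st)
  # every form contributes its serpin chain, two domains in both modes,
  # sheets and RCL; complexes add 4 more rows
  n_complex <- sum(vapply(fx$config$forms,
                          function(f) length(f$protease_chains) > 0, logical(1)))
  expect_equal(nrow(res),
               5 * (1 + 4) + sum(vapply(fx$config$forms,
                                        function(f) length(f$sheets), integer(1))) +
                 5 + 4 * n_complex)
  ok <- res[is.na(res$note), ]
  expect_true(all(is.finite(ok$rd)))
  expect_true(all(ok$rd >= 0 & ok$rd <= 1))
  expect_equal(nrow(st$bfactor), 10)           # 5 forms x 2 domains
  # dropping one structure flags its rows but keeps the others
  st2 <- run_study(fx$config, fx$structures[-2])
  res2 <- tidy(st2)
  expect_true(any(res2$note == "structure not supplied", na.rm = TRUE))
  expect_equal(sum(is.na(res2$note)), sum(is.na(res$note)) -
                 sum(is.na(res$note[res$pdb_id == "SYN2"]))
  )
})

test_that("study reports are byte-identical across repeated runs", {
  fx <- make_study_fixture(seed = 32, n = 60)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_tsv(run_study(fx$config, fx$structures), d1)
  write_study_tsv(run_study(fx$config, fx$structures), d2)
  for (f in c("study_results.tsv", "study_bfactor.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the packaged serpin configuration loads and its selections parse", {
  cfg <- serpin_study_config()
  expect_equal(length(cfg$forms), 5)
  expect_setequal(vapply(cfg$forms, `[[`, "", "pdb_id"),
                  c("1QLP", "2ANT", "1K9O", "1EZX", "7API"))
  # every sheet range parses into valid inclusive intervals
  for (f in cfg$forms) {
    for (sh in f$sheets) {
      sel <- fodm_selection(sh$name, sh$ranges, role = "beta_sheet")
      expect_true(all(sel$intervals$start <= sel$intervals$end))
    }
  }
  # the native-form sheet A spans 43 residues when no residues are missing
  native <- cfg$forms[[1]]
  sheet_a <- native$sheets[[1]]$ranges
  s <- numbered_structure(100:400)
  expect_equal(nrow(apply_selection(s, sheet_a)), 43)
  # incorporated variants strictly extend their no-incorporation counterparts
  cleaved <- cfg$forms[[5]]
  sheets <- setNames(lapply(cleaved$sheets, `[[`, "ranges"),
                     vapply(cleaved$sheets, `[[`, "", "name"))
  expect_true(nchar(sheets[["sheet_A_incorp"]]) > nchar(sheets[["sheet_A"]]))
})
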