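test_that("subsumes follows the two-level hierarchy", {
  expect_true(subsumes(HIER, "RT", "RT_LTR"))
  expect_true(subsumes(HIER, "RT_LTR", "RT_LTR"))
  expect_false(subsumes(HIER, "GAG", "RT_LTR"))
  expect_false(subsumes(HIER, "RT_LTR", "RVT_1"))
  expect_error(subsumes(HIER, "NOPE", "RT_LTR"), "unknown domain")
  expect_error(subsumes(HIER, "RT", "RT"), "must be a subdomain")
  # vectorised over hits
  expect_equal(subsumes(HIER, "AP", c("RVP_2", "rve", "Peptidase_A17")),
               c(TRUE, FALSE, TRUE))
})

test_that("enumerate_tests matches a brute-force oracle on a toy vocabulary", {
  voc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("general\tsubdomain\taccession",
               "G1\tS1\tx1", "G1\tS2\tx2"), voc)
  toy_h <- ltr_hierarchy(voc)
  toy_cfg <- run_config(evalue_grid = c(1e-10, 1e-2),
                        length_grid = 100L, count_grid = 1:2)
  tt <- enumerate_tests(toy_h, toy_cfg)

  # brute-force enumeration over the cross-product, deduplicated as strings
  doms <- c("S1", "S2", "G1")
  evs <- c(1e-10, 1e-2)
  brute <- character(0)
  for (d in doms) for (e in evs) brute <- c(brute, paste("O", d, e))
  for (d in doms) for (e in evs) for (dir in c("min", "max"))
    brute <- c(brute, paste("L", d, e, dir, 100))
  for (d1 in doms) for (d2 in doms) for (e in evs)
    brute <- c(brute, paste("B", d1, d2, e))
  for (thr in 1:2) brute <- c(brute, paste("C", "G1", thr))
  expect_equal(nrow(tt), length(unique(brute)))   # 6 + 12 + 18 + 2 = 38
  expect_equal(nrow(tt), 38L)

  # duplicate-free and stable across calls
  key <- paste(tt$variant, tt$domain, tt$domain2, tt$evalue, tt$len_dir,
               tt$len_limit, tt$count_thr)
  expect_false(anyDuplicated(key) > 0L)
  expect_identical(tt, enumerate_tests(toy_h, toy_cfg))

  # empty e-value grid empties the three hit-qualifying families
  tt0 <- enumerate_tests(toy_h, run_config(evalue_grid = numeric(0),
                                           length_grid = 100L,
                                           count_grid = 1:2))
  expect_equal(unique(tt0$variant), "COUNT")
  expect_equal(nrow(tt0), 2L)
})

test_that("single-child generals are extensional duplicates and are dropped", {
  expect_false("Integrase" %in% HIER$test_domains)
  expect_false("Pre-integrase" %in% HIER$test_domains)
  expect_length(HIER$test_domains, 31L)
  # with deduplication off, the redundant generals reappear
  tt_all <- enumerate_tests(HIER, CFG, dedup_extensional = FALSE)
  expect_true("Integrase" %in% tt_all$domain)
  expect_equal(sum(tt_all$variant == "OCCURS"), 33L * 8L)
  # and an Integrase test is extensionally identical to its rve twin
  cand <- mk_cand(mk_hits("c", "rve", 100, 400, evalue = 1e-20))
  ti <- tt_all[tt_all$variant == "OCCURS" & tt_all$domain == "Integrase" &
                 tt_all$evalue == 1e-10, ]
  tr <- tt_all[tt_all$variant == "OCCURS" & tt_all$domain == "rve" &
                 tt_all$evalue == 1e-10, ]
  expect_equal(evaluate_test(cand, ti, HIER), evaluate_test(cand, tr, HIER))
})

test_that("evaluate_test implements the four families' semantics", {
  # occurrence via subsumption, with the e-value ceiling
  cand <- mk_cand(mk_hits("c", "RT_LTR", 100, 600, evalue = 1e-12))
  expect_true(evaluate_test(cand, pick_test("OCCURS", "RT", 1e-10), HIER))
  expect_false(evaluate_test(cand, pick_test("OCCURS", "RT", 1e-20), HIER))
  expect_false(evaluate_test(cand, pick_test("OCCURS", "GAG", 1e-01), HIER))

  # length bounds apply to the qualifying hit itself
  cand <- mk_cand(mk_hits("c", "Retrotrans_gag", 100, 249, evalue = 1e-8))
  expect_false(evaluate_test(
    cand, pick_test("OCCURS_LEN", "GAG", 1e-05, len_dir = "min",
                    len_limit = 200L), HIER))
  expect_true(evaluate_test(
    cand, pick_test("OCCURS_LEN", "GAG", 1e-05, len_dir = "max",
                    len_limit = 200L), HIER))
  cand2 <- mk_cand(mk_hits("c", "Retrotrans_gag", 100, 299, evalue = 1e-8))
  expect_true(evaluate_test(
    cand2, pick_test("OCCURS_LEN", "GAG", 1e-05, len_dir = "min",
                     len_limit = 200L), HIER))

  # precedence by start order
  cand <- mk_cand(mk_hits("c", c("retropepsin_like", "RT_LTR"),
                          c(300, 900), c(600, 1400), evalue = 1e-5))
  expect_true(evaluate_test(cand, pick_test("BEFORE", "AP", 1e-02,
                                            domain2 = "RT"), HIER))
  expect_false(evaluate_test(cand, pick_test("BEFORE", "RT", 1e-02,
                                             domain2 = "AP"), HIER))
  # on the minus strand the element order is reversed
  mcand <- mk_cand(mk_hits("c", c("retropepsin_like", "RT_LTR"),
                           c(300, 900), c(600, 1400), strand = "-",
                           evalue = 1e-5))
  expect_false(evaluate_test(mcand, pick_test("BEFORE", "AP", 1e-02,
                                              domain2 = "RT"), HIER))
  expect_true(evaluate_test(mcand, pick_test("BEFORE", "RT", 1e-02,
                                             domain2 = "AP"), HIER))

  # counts are strict and ignore e-values
  cand <- mk_cand(mk_hits("c", c("RNase_HI_like", "RNase_HI_RT_Ty3"),
                          c(100, 900), c(400, 1200), evalue = c(1, 1)))
  expect_false(evaluate_test(cand, pick_test("COUNT", "RNase",
                                             count_thr = 2L), HIER))
  expect_true(evaluate_test(cand, pick_test("COUNT", "RNase",
                                            count_thr = 1L), HIER))
})

test_that("qualifying-hit tests are monotone in the e-value ceiling", {
  withr::local_seed(99)
  sweep_tests <- TESTS[TESTS$variant != "COUNT", ]
  for (i in 1:10) {
    cand <- mk_cand(fuzz_candidate(paste0("m", i)))
    for (v in c("OCCURS", "OCCURS_LEN", "BEFORE")) {
      tv <- sweep_tests[sweep_tests$variant == v, ]
      # fix everything but the e-value; truth must be non-decreasing
      grp <- paste(tv$domain, tv$domain2, tv$len_dir, tv$len_limit)
      pickgrp <- sample(unique(grp), 5L)
      for (g in pickgrp) {
        rows <- tv[grp == g, ]
        rows <- rows[order(rows$evalue), ]
        vals <- vapply(seq_len(nrow(rows)), function(j)
          evaluate_test(cand, rows[j, ], HIER), logical(1L))
        expect_true(all(diff(as.integer(vals)) >= 0L))
      }
    }
  }
})

test_that("cached evaluation agrees with the naive oracle on fuzz candidates", {
  withr::local_seed(4242)
  sub <- TESTS[sort(sample.int(nrow(TESTS), 400L)), ]
  for (i in 1:12) {
    hits <- fuzz_candidate(paste0("f", i))
    cand <- mk_cand(hits)
    got <- as.logical(evaluate_tests(cand, sub, HIER, CFG))
    want <- oracle_eval_all(hits, sub)
    expect_identical(got, want)
  }
})
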