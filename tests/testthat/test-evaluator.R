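mk_pred <- function(start, end, prob = 1, label = "Gypsy", seq_id = "chr1") {
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = "+", label = label, prob = prob,
             stringsAsFactors = FALSE)
}
mk_ann <- function(start, end, label = "Gypsy", seq_id = "chr1",
                   id = sprintf("a%02d", seq_along(start))) {
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = "+", label = label, id = id,
             stringsAsFactors = FALSE)
}

test_that("the 100-nt / containment true-positive rule", {
  # 50 nt overlap: below threshold
  m <- match_annotations(mk_pred(1000, 1099), mk_ann(1050, 2000))
  expect_false(m$pred_tp)
  # exactly 100 nt overlap (min(e) - max(s) + 1)
  m <- match_annotations(mk_pred(1000, 1300), mk_ann(1201, 1400))
  expect_true(m$pred_tp)
  # full containment counts regardless of overlap length, both directions
  m <- match_annotations(mk_pred(1000, 5000), mk_ann(2000, 2050))
  expect_true(m$pred_tp)
  m <- match_annotations(mk_pred(2000, 2050), mk_ann(1000, 5000))
  expect_true(m$pred_tp)
  # labels must agree; seq_ids must agree
  m <- match_annotations(mk_pred(1000, 1300, label = "Copia"),
                         mk_ann(1201, 1400))
  expect_false(m$pred_tp)
  m <- match_annotations(mk_pred(1000, 1300, seq_id = "chr2"),
                         mk_ann(1201, 1400))
  expect_false(m$pred_tp)
  # an annotation counts once however many predictions hit it
  m <- match_annotations(rbind(mk_pred(1000, 1300), mk_pred(1100, 1400)),
                         mk_ann(1000, 1400))
  expect_equal(sum(m$ann_found), 1L)
  expect_equal(m$pred_tp, c(TRUE, TRUE))
  # monotone in min_overlap: a larger threshold never creates new TPs
  preds <- mk_pred(c(1000, 3000, 7000), c(1500, 3219, 7080))
  anns <- mk_ann(c(1400, 3100, 7050), c(2600, 3600, 7500))
  for (ov in c(50L, 100L, 150L, 600L)) {
    lo <- match_annotations(preds, anns, ov)
    hi <- match_annotations(preds, anns, ov + 50L)
    expect_true(all(lo$pred_tp >= hi$pred_tp))
  }
})

test_that("pr_curve reproduces the hand-enumerated example", {
  anns <- mk_ann(c(1000, 5000, 9000, 13000), c(2000, 6000, 10000, 14000))
  preds <- rbind(
    mk_pred(1000, 1500, prob = 0.9),    # TP on a01
    mk_pred(20000, 20500, prob = 0.8),  # FP
    mk_pred(5000, 5500, prob = 0.6))    # TP on a02
  curve <- pr_curve(preds, anns)
  expect_equal(curve$threshold, c(0.9, 0.8, 0.6))
  expect_equal(curve$precision, c(1.0, 0.5, 2 / 3))
  expect_equal(curve$recall, c(0.25, 0.25, 0.5))
  expect_equal(max_f1(curve), 4 / 7)
  expect_equal(attr(curve, "annotation_total"), 4L)

  # all-TP predictions keep precision at 1 along the curve
  curve <- pr_curve(preds[c(1, 3), ], anns)
  expect_true(all(curve$precision == 1))
  # a prediction matching nothing gives a flat zero-precision curve
  curve <- pr_curve(mk_pred(20000, 20100, prob = 0.7), anns)
  expect_true(all(curve$precision == 0))
  expect_true(all(curve$recall == 0))
  expect_equal(max_f1(curve), 0)

  expect_error(pr_curve(preds, anns[0, ]), "zero annotations")
})

test_that("pr_curve agrees with brute-force re-evaluation at every threshold", {
  withr::local_seed(314)
  for (rep in 1:5) {
    np <- sample(5:20, 1L)
    na <- sample(3:10, 1L)
    anns <- mk_ann(seq_len(na) * 3000L, seq_len(na) * 3000L + 800L)
    s <- sample.int(na * 3000L + 2000L, np)
    preds <- mk_pred(s, s + sample(100:900, np, replace = TRUE),
                     prob = round(runif(np), 2))
    curve <- pr_curve(preds, anns)
    expect_true(all(diff(curve$recall) >= 0))  # recall non-decreasing
    for (k in seq_len(nrow(curve))) {
      t <- curve$threshold[k]
      sel <- preds[preds$prob >= t, , drop = FALSE]
      m <- match_annotations(sel, anns)
      expect_equal(curve$precision[k], mean(m$pred_tp))
      expect_equal(curve$recall[k], mean(m$ann_found))
    }
  }
})

test_that("combined_pr uses the None-aware denominators", {
  anns <- rbind(mk_ann(1000, 2000, label = "Copia"),
                mk_ann(5000, 6000, label = "Gypsy", id = "a02"))
  rec <- data.frame(candidate_id = c("c1", "c2"), seq_id = "chr1",
                    start = c(1000L, 9000L), end = c(1800L, 9400L),
                    strand = "+", stringsAsFactors = FALSE)
  rec$Copia <- c(0.9, 0.2); rec$Gypsy <- c(0.1, 0.3)
  curve <- combined_pr(rec, anns)
  # at t = 0.9 only the correct Copia prediction is non-None
  k <- which(curve$threshold == 0.9)
  expect_equal(curve$precision[k], 1.0)
  expect_equal(curve$recall[k], 0.5)
  # at t = 0.3 the second prediction (argmax Gypsy, no match) joins
  k <- which(curve$threshold == 0.3)
  expect_equal(curve$precision[k], 0.5)
  expect_equal(curve$recall[k], 0.5)

  # a correct-looking prediction with the wrong label is an FP
  rec2 <- rec[1, ]; rec2$Copia <- 0.1; rec2$Gypsy <- 0.9
  curve <- combined_pr(rec2, anns)   # overlaps the Copia annotation only
  expect_true(all(curve$precision == 0))

  # zero predictions -> empty curve rather than an error
  expect_equal(nrow(combined_pr(rec[0, ], anns)), 0L)
  expect_error(combined_pr(rec, anns[0, ]), "zero annotations")
})

test_that("exclusive_comparison partitions the found annotations", {
  anns <- mk_ann(c(1000, 5000, 9000), c(2000, 6000, 10000))
  pa <- rbind(mk_pred(1000, 1500), mk_pred(5000, 5500))   # finds a01, a02
  pb <- rbind(mk_pred(5200, 5700), mk_pred(9000, 9500))   # finds a02, a03
  ma <- match_annotations(pa, anns)
  mb <- match_annotations(pb, anns)
  expect_equal(unname(exclusive_comparison(ma, mb)), c(1L, 1L, 1L))
  expect_equal(unname(exclusive_comparison(ma, ma)),
               c(0L, sum(ma$ann_found), 0L))
  m0 <- match_annotations(pa[0, ], anns)
  expect_equal(unname(exclusive_comparison(ma, m0)), c(2L, 0L, 0L))
  # only_a + both equals the number found by A, whatever the order
  mb2 <- match_annotations(pb[2:1, ], anns)
  expect_identical(exclusive_comparison(ma, mb2), exclusive_comparison(ma, mb))
  expect_error(exclusive_comparison(ma, match_annotations(pa, anns[1:2, ])),
               "consistency error")
})

test_that("PR tables round-trip through the TSV writer", {
  anns <- mk_ann(c(1000, 5000), c(2000, 6000))
  curve <- pr_curve(rbind(mk_pred(1000, 1500, 0.9), mk_pred(5000, 5400, 0.4)),
                    anns)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pr_table(curve, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$precision, curve$precision)
  expect_equal(back$recall, curve$recall)
})
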