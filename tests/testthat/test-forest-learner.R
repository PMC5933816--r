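test_that("assemble_training_set balances, filters and is seed-deterministic", {
  # 5 Copia / 20 Gypsy: negatives sampled down to the positive count
  big <- mk_corpus(5L, 20L)
  ex <- assemble_training_set(big, "Copia", seed = 3)
  expect_equal(sum(ex$labels), 5L)
  expect_equal(sum(!ex$labels), 5L)
  expect_identical(ex$ids, assemble_training_set(big, "Copia", seed = 3)$ids)
  expect_false(identical(ex$ids,
                         assemble_training_set(big, "Copia", seed = 4)$ids))

  # 20 Copia / 5 Gypsy: all available negatives are kept
  ex <- assemble_training_set(mk_corpus(20L, 5L), "Copia", seed = 1)
  expect_equal(sum(ex$labels), 20L)
  expect_equal(sum(!ex$labels), 5L)

  # hit-free and mixed-strand sequences are filtered before sampling
  corp <- mk_corpus(3L, 3L)
  corp$labels <- c(corp$labels, nohit = "Gypsy", mixed = "Gypsy")
  corp$hits <- rbind(corp$hits,
                     mk_hits("mixed", c("rve", "RT_LTR"), c(1, 500),
                             c(300, 900), strand = c("+", "-")))
  ex <- assemble_training_set(corp, "Copia", seed = 1)
  expect_false(any(c("nohit", "mixed") %in% ex$ids))

  corp$labels <- corp$labels[corp$labels != "Copia"]
  expect_error(assemble_training_set(corp, "Copia"),
               "no positive training sequences")
})

test_that("induce_tree handles pure nodes and the min-leaf floor", {
  # all positive -> single leaf with p = 1
  corp <- mk_corpus(6L, 6L)
  ex <- assemble_training_set(corp, "Copia", seed = 1)
  ex$labels[] <- TRUE
  tree <- induce_tree(ex, CFG, HIER, tests = TESTS)
  expect_true(tree$leaf)
  expect_equal(tree$pos / tree$n, 1.0)

  # 7 examples (4 pos, 3 neg), min_leaf 5 -> no split can keep 5 a side
  ex7 <- example_set(ex$ids[1:7], ex$hits[ex$hits$source_seq %in% ex$ids[1:7], ],
                     labels = setNames(c(rep(TRUE, 4), rep(FALSE, 3)),
                                       ex$ids[1:7]))
  tree <- induce_tree(ex7, CFG, HIER, tests = TESTS)
  expect_true(tree$leaf)
  expect_equal(tree$n, 7L)
  expect_equal(tree$pos / tree$n, 4 / 7)
})

test_that("with sampling disabled the root split is gain-optimal", {
  # 12 examples where occurs(RNase_HI_RT_Ty1, e<=1e-05) separates perfectly
  ids <- sprintf("e%02d", 1:12)
  y <- rep(c(TRUE, FALSE), each = 6L)
  hits <- rbind(
    mk_hits(ids[1:6], "RNase_HI_RT_Ty1", 100, 400, evalue = 1e-8),
    mk_hits(ids[7:12], "Retrotran_gag_2", 100, 400, evalue = 1e-8))
  ex <- example_set(ids, hits, labels = setNames(y, ids))
  cfg <- run_config(min_leaf = 5L)
  tree <- induce_tree(ex, cfg, HIER, tests = TESTS, sample_features = FALSE)
  expect_false(tree$leaf)
  # chosen root must score the exhaustive-search optimum (ties allowed)
  hb <- split(hits, factor(hits$source_seq, levels = ids))
  oracle <- oracle_best_split(hb, y, TESTS, cfg$min_leaf)
  M <- evaluate_tests(ex, TESTS[c(tree$test, oracle$best), ], HIER, cfg)
  gain_of <- function(col) {
    nyes <- sum(col); pyes <- sum(col & y)
    oracle_entropy(mean(y)) -
      (nyes / 12) * oracle_entropy(pyes / max(nyes, 1)) -
      ((12 - nyes) / 12) * oracle_entropy((sum(y) - pyes) / max(12 - nyes, 1))
  }
  expect_equal(gain_of(M[, 1L]), oracle$gain, tolerance = 1e-12)
  expect_equal(gain_of(M[, 1L]), 1.0, tolerance = 1e-12)  # perfect split
  # both children are pure leaves
  expect_true(tree$yes$leaf && tree$no$leaf)
  expect_equal(tree$yes$pos / tree$yes$n + tree$no$pos / tree$no$n, 1.0)
})

test_that("forests are deterministic and degenerate to a single tree", {
  corp <- mk_corpus(10L, 10L)
  ex <- assemble_training_set(corp, "Copia", seed = 2)
  cfg <- run_config(n_trees = 4L, min_leaf = 2L)
  f1 <- induce_forest(ex, cfg, HIER, target = "Copia", seed = 11)
  f2 <- induce_forest(ex, cfg, HIER, target = "Copia", seed = 11)
  expect_identical(f1$trees, f2$trees)
  f3 <- induce_forest(ex, cfg, HIER, target = "Copia", seed = 12)
  expect_false(identical(f1$trees, f3$trees) &&
                 identical(f1$inbag, f3$inbag))

  cfg1 <- run_config(n_trees = 1L, min_leaf = 2L)
  f <- induce_forest(ex, cfg1, HIER, target = "Copia", seed = 5,
                     bootstrap = FALSE, sample_features = FALSE)
  tree <- induce_tree(ex, cfg1, HIER, sample_features = FALSE)
  expect_identical(f$trees[[1L]], tree)
  cands <- example_set(ex$ids, ex$hits)
  expect_identical(unname(predict_proba(f, cands, HIER)),
                   unname(forest_tree_predictions(f, cands, HIER)[, 1L]))
})

test_that("predict_proba averages leaf frequencies across trees", {
  leaf <- function(n, pos) list(leaf = TRUE, n = n, pos = pos)
  fake <- structure(list(
    format = "ltrforest-model", version = 1L, target = "Copia",
    params = list(evalue_grid = CFG$evalue_grid,
                  length_grid = CFG$length_grid,
                  count_grid = CFG$count_grid, min_leaf = 5L, n_trees = 2L,
                  seed = 1L, bootstrap = TRUE, sample_features = TRUE,
                  dedup_extensional = TRUE, pair_repetition = TRUE,
                  split_criterion = "information_gain",
                  aggregation = "mean_leaf_frequency"),
    n_tests = nrow(TESTS),
    trees = list(leaf(10L, 9L), leaf(10L, 7L)), inbag = NULL),
    class = "ltr_forest")
  cand <- mk_cand(mk_hits("c", "rve", 1, 300))
  expect_equal(unname(predict_proba(fake, cand, HIER)), 0.8)
  fake$trees <- list(leaf(5L, 5L), leaf(7L, 7L), leaf(9L, 9L))
  expect_equal(unname(predict_proba(fake, cand, HIER)), 1.0)
})

test_that("min_leaf bounds every leaf and usage stats sum to one", {
  specs <- order_task_architectures(dropout = 0.15)
  corp <- simulate_training_corpus(specs, 60L, seed = 31)
  ex <- assemble_training_set(corp, "Copia", seed = 1)
  cfg <- run_config(n_trees = 10L)
  f <- induce_forest(ex, cfg, HIER, target = "Copia", seed = 8)
  min_leaf_n <- function(node) {
    if (node$leaf) return(node$n)
    min(min_leaf_n(node$yes), min_leaf_n(node$no))
  }
  expect_true(all(vapply(f$trees, min_leaf_n, numeric(1)) >= 5))
  st <- node_usage_stats(f, HIER)
  expect_equal(sum(st), 1.0)
  expect_named(st, c("OCCURS", "OCCURS_LEN", "BEFORE", "COUNT"))
})

test_that("the ensemble is no worse than a single tree on held-out data", {
  specs <- order_task_architectures(dropout = 0.2)
  train <- simulate_training_corpus(specs, 150L, seed = 77)
  hold <- simulate_training_corpus(specs, 100L, seed = 78)
  ex <- assemble_training_set(train, "Copia", seed = 1)
  hx <- example_set(names(hold$labels), hold$hits)
  truth <- hold$labels == "Copia"
  cfg <- run_config(n_trees = 30L)
  forest <- induce_forest(ex, cfg, HIER, target = "Copia", seed = 21)
  acc_forest <- mean((predict_proba(forest, hx, HIER) > 0.5) == truth)
  tree <- induce_tree(ex, cfg, HIER, sample_features = FALSE)
  f1 <- forest; f1$trees <- list(tree)
  acc_tree <- mean((predict_proba(f1, hx, HIER) > 0.5) == truth)
  expect_gte(acc_forest, acc_tree - 0.02)
  # training accuracy should not fall below holdout accuracy (sanity)
  acc_train <- mean((predict_proba(forest,
                                   example_set(ex$ids, ex$hits), HIER) > 0.5)
                    == ex$labels)
  expect_gte(acc_train, acc_forest - 0.02)
})
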