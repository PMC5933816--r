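#' Training-example container
#'
#' @param ids Example identifiers.
#' @param hits Hit `data.frame` (`source_seq` in `ids`), sequence-local
#'   coordinates, one strand per example.
#' @param labels Logical vector parallel to `ids` (TRUE = positive for the
#'   target superfamily), or NULL for unlabelled sets.
#' @return Object of class `ltr_examples`.
#' @export
example_set <- function(ids, hits, labels = NULL) {
  stopifnot(is.null(labels) || length(labels) == length(ids))
  structure(list(ids = ids, hits = hits, labels = labels),
            class = "ltr_examples")
}

# evaluate with or restore RNG state around a seeded computation
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assemble a balanced one-vs-rest training set
#'
#' Positives are all corpus sequences of the target superfamily that survive
#' the filters (at least one domain hit; hits on a single strand). Negatives
#' are sampled without replacement from the other superfamilies to the same
#' size; if fewer are available, all of them are used (still an approximately
#' balanced task).
#'
#' @param corpus List with `hits` (hit `data.frame`) and `labels` (named
#'   character vector, sequence id -> superfamily), e.g. from
#'   [simulate_training_corpus()].
#' @param target Target superfamily.
#' @param seed Integer seed making the negative sampling deterministic.
#' @return An `ltr_examples` set with logical labels.
#' @export
assemble_training_set <- function(corpus, target, seed = 1L) {
  stopifnot(target %in% superfamilies())
  labels <- corpus$labels
  ids <- names(labels)
  keep <- vapply(ids, function(id) {
    h <- corpus$hits[corpus$hits$source_seq == id, , drop = FALSE]
    nrow(h) >= 1L && length(unique(h$strand)) == 1L
  }, logical(1L))
  ids <- ids[keep]
  pos_ids <- ids[labels[ids] == target]
  neg_pool <- ids[labels[ids] != target]
  if (!length(pos_ids))
    stop("configuration error: no positive training sequences for ", target)
  neg_ids <- if (length(neg_pool) <= length(pos_ids)) neg_pool else
    with_seed(seed, sort(sample(neg_pool, length(pos_ids))))
  sel <- c(pos_ids, neg_ids)
  example_set(sel,
              corpus$hits[corpus$hits$source_seq %in% sel, , drop = FALSE],
              labels = stats::setNames(labels[sel] == target, sel))
}

entropy2 <- function(p) {
  q <- 1 - p
  h <- numeric(length(p))
  nz <- p > 0 & p < 1
  h[nz] <- -p[nz] * log2(p[nz]) - q[nz] * log2(q[nz])
  h
}

# split scores for a boolean test matrix M (rows = examples at the node)
split_gains <- function(M, y, min_leaf) {
  n <- nrow(M)
  npos <- sum(y)
  nyes <- colSums(M)
  pyes <- as.numeric(crossprod(M, y))   # positives routed to yes
  nno <- n - nyes
  pno <- npos - pyes
  valid <- nyes >= min_leaf & nno >= min_leaf
  gain <- entropy2(npos / n) -
    (nyes / n) * entropy2(ifelse(nyes > 0, pyes / nyes, 0)) -
    (nno / n) * entropy2(ifelse(nno > 0, pno / nno, 0))
  gain[!valid] <- -Inf
  gain
}

build_node <- function(rows, y, cache, tests, min_leaf, n_feat) {
  n <- length(rows)
  npos <- sum(y[rows])
  make_leaf <- function() list(leaf = TRUE, n = n, pos = npos)
  if (npos == 0L || npos == n || n < 2L * min_leaf) return(make_leaf())
  tryidx <- if (is.null(n_feat) || n_feat >= nrow(tests)) seq_len(nrow(tests))
            else sort(sample.int(nrow(tests), n_feat))
  M <- eval_tests_cached(cache, tests[tryidx, , drop = FALSE], rows)
  gains <- split_gains(M, y[rows], min_leaf)
  best <- which.max(gains)             # first (canonical-order) maximum
  if (!length(best) || gains[best] <= 1e-12) return(make_leaf())
  go_yes <- M[, best]
  list(leaf = FALSE, test = tryidx[best],
       yes = build_node(rows[go_yes], y, cache, tests, min_leaf, n_feat),
       no  = build_node(rows[!go_yes], y, cache, tests, min_leaf, n_feat))
}

#' Induce a single relational decision tree
#'
#' Standard top-down induction, no pruning. At each node a random sample of
#' `ceiling(sqrt(#tests))` tests is scored by information gain (class-entropy
#' reduction); the best valid split (both branches keeping at least
#' `min_leaf` examples, strictly positive gain) is installed, ties resolved
#' by canonical enumeration order. A node becomes a leaf when pure, when it
#' holds fewer than `2 * min_leaf` examples, or when no sampled test splits
#' validly; the leaf stores the raw empirical class counts.
#'
#' @param examples `ltr_examples` with logical labels.
#' @param cfg An `ltr_config` (`min_leaf`, grids).
#' @param hierarchy An `ltr_hierarchy`.
#' @param tests Enumerated test table; defaults to
#'   `enumerate_tests(hierarchy, cfg)`.
#' @param sample_features FALSE scores every test at every node (used by the
#'   split-selection oracle checks); TRUE uses sqrt-sampling.
#' @param rows Example indices (with repetition for bootstrap resamples).
#' @param cache Prebuilt feature cache (built from `examples` if NULL).
#' @return Tree root (nested list; internal nodes carry the canonical test
#'   index, leaves carry `n` and `pos` counts).
#' @export
induce_tree <- function(examples, cfg, hierarchy,
                        tests = enumerate_tests(hierarchy, cfg),
                        sample_features = TRUE,
                        rows = seq_along(examples$ids),
                        cache = NULL) {
  stopifnot(!is.null(examples$labels))
  if (is.null(cache))
    cache <- build_feature_cache(examples$ids, examples$hits, hierarchy, cfg,
                                 test_domains = attr(tests, "test_domains") %||%
                                   hierarchy$test_domains)
  n_feat <- if (isTRUE(sample_features)) ceiling(sqrt(nrow(tests))) else NULL
  build_node(rows, unname(examples$labels), cache, tests, cfg$min_leaf, n_feat)
}

#' Induce a relational random forest
#'
#' `n_trees` trees, each grown on a bootstrap resample (with replacement, to
#' the original size) with sqrt-feature sampling at every node. Fully
#' reproducible under `seed`.
#'
#' @inheritParams induce_tree
#' @param target Superfamily the forest scores (metadata).
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @param bootstrap FALSE trains every tree on the full sample (a 1-tree
#'   forest then equals [induce_tree()]).
#' @return Object of class `ltr_forest` with elements `trees`, `target`,
#'   `params` (grids and learner settings, frozen enumeration configuration),
#'   `n_tests`, and the in-bag index list `inbag` (not serialized).
#' @export
induce_forest <- function(examples, cfg, hierarchy, target = NA_character_,
                          seed = cfg$rng_seed,
                          tests = enumerate_tests(hierarchy, cfg),
                          bootstrap = TRUE, sample_features = TRUE) {
  cache <- build_feature_cache(examples$ids, examples$hits, hierarchy, cfg,
                               test_domains = attr(tests, "test_domains") %||%
                                 hierarchy$test_domains)
  n <- length(examples$ids)
  trees <- vector("list", cfg$n_trees)
  inbag <- vector("list", cfg$n_trees)
  with_seed(seed, {
    for (b in seq_len(cfg$n_trees)) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      inbag[[b]] <- rows
      trees[[b]] <- build_node(rows, unname(examples$labels), cache, tests,
                               cfg$min_leaf,
                               if (sample_features) ceiling(sqrt(nrow(tests)))
                               else NULL)
    }
  })
  structure(list(
    format = "ltrforest-model", version = 1L,
    target = target,
    params = list(evalue_grid = cfg$evalue_grid,
                  length_grid = cfg$length_grid,
                  count_grid = cfg$count_grid,
                  min_leaf = cfg$min_leaf,
                  n_trees = cfg$n_trees,
                  seed = as.integer(seed),
                  bootstrap = bootstrap,
                  sample_features = sample_features,
                  dedup_extensional = isTRUE(attr(tests, "dedup_extensional")),
                  pair_repetition = isTRUE(attr(tests, "pair_repetition")),
                  split_criterion = "information_gain",
                  aggregation = "mean_leaf_frequency"),
    n_tests = nrow(tests),
    trees = trees,
    inbag = inbag
  ), class = "ltr_forest")
}

#' @export
print.ltr_forest <- function(x, ...) {
  cat("Relational random forest for", x$target, "-", length(x$trees),
      "trees over", x$n_tests, "node tests\n")
  invisible(x)
}

forest_config <- function(forest, base = run_config()) {
  base$evalue_grid <- forest$params$evalue_grid
  base$length_grid <- as.integer(forest$params$length_grid)
  base$count_grid <- as.integer(forest$params$count_grid)
  base$min_leaf <- as.integer(forest$params$min_leaf)
  base$n_trees <- as.integer(forest$params$n_trees)
  base
}

forest_tests <- function(forest, hierarchy) {
  enumerate_tests(hierarchy, forest_config(forest),
                  dedup_extensional = forest$params$dedup_extensional,
                  pair_repetition = forest$params$pair_repetition)
}

route_tree <- function(tree, cache, tests, rows, out) {
  if (tree$leaf) {
    out[rows] <- if (tree$n > 0) tree$pos / tree$n else 0.5
    return(out)
  }
  if (!length(rows)) return(out)
  go <- eval_test_cached(cache, tests[tree$test, ], rows)
  out <- route_tree(tree$yes, cache, tests, rows[go], out)
  route_tree(tree$no, cache, tests, rows[!go], out)
}

#' Per-tree leaf probabilities for a candidate set
#'
#' @param forest `ltr_forest`.
#' @param candidates `ltr_candidates` or `ltr_examples`.
#' @param hierarchy `ltr_hierarchy`.
#' @return Numeric matrix, candidates in rows, trees in columns.
#' @export
forest_tree_predictions <- function(forest, candidates, hierarchy) {
  cfg <- forest_config(forest)
  tests <- forest_tests(forest, hierarchy)
  cache <- build_feature_cache(candidates$ids, candidates$hits, hierarchy, cfg,
                               test_domains = attr(tests, "test_domains"))
  n <- length(candidates$ids)
  out <- matrix(NA_real_, n, length(forest$trees),
                dimnames = list(candidates$ids, NULL))
  for (b in seq_along(forest$trees))
    out[, b] <- route_tree(forest$trees[[b]], cache, tests, seq_len(n),
                           numeric(n))
  out
}

#' Forest probability for candidates
#'
#' Mean over trees of the empirical positive frequency of the leaf each
#' candidate is routed to.
#'
#' @inheritParams forest_tree_predictions
#' @return Named numeric vector in `[0, 1]`.
#' @export
predict_proba <- function(forest, candidates, hierarchy) {
  rowMeans(forest_tree_predictions(forest, candidates, hierarchy))
}

#' Node-test usage statistics of a forest
#'
#' Proportion of internal nodes using each test family, across all trees.
#' @param forest `ltr_forest`.
#' @param hierarchy `ltr_hierarchy`.
#' @return Named numeric vector over the four families, summing to 1.
#' @export
node_usage_stats <- function(forest, hierarchy) {
  tests <- forest_tests(forest, hierarchy)
  counts <- c(OCCURS = 0, OCCURS_LEN = 0, BEFORE = 0, COUNT = 0)
  walk <- function(node) {
    if (node$leaf) return(invisible())
    v <- tests$variant[node$test]
    counts[v] <<- counts[v] + 1
    walk(node$yes); walk(node$no)
  }
  for (tr in forest$trees) walk(tr)
  if (sum(counts) == 0) counts else counts / sum(counts)
}
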