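#' Enumerate the relational node-test language
#'
#' Builds the complete, duplicate-free, canonically ordered set of node tests
#' available to the tree learner. Four families:
#'
#' * `OCCURS(d, e)` — some hit of domain `d` (subsumption-aware) has
#'   e-value `<= e`;
#' * `OCCURS_LEN(d, e, dir, L)` — as above, with the hit's length
#'   (`end - start + 1`) additionally `>= L` (`dir = "min"`) or `<= L`
#'   (`dir = "max"`);
#' * `BEFORE(d1, d2, e)` — two qualifying hits (e-value `<= e` each, and
#'   distinct when `d1 == d2`) with the first's start strictly before the
#'   second's, in element orientation;
#' * `COUNT(g, k)` — the number of hits under general domain `g` (any
#'   e-value) strictly exceeds `k`.
#'
#' Domains for the first three families are the extensionally distinct
#' identifiers of the hierarchy (subdomains plus multi-child generals; a
#' single-child general duplicates its subdomain's tests and is skipped so
#' the enumeration is duplicate-free). Precedence pairs are ordered and allow
#' `d1 == d2`. Under the default vocabulary and grids this yields exactly
#' 10,947 tests: 31*8 = 248 occurrence, 31*8*12 = 2,976 length,
#' 31^2*8 = 7,688 precedence and 7*5 = 35 count tests.
#'
#' @param hierarchy An `ltr_hierarchy`.
#' @param cfg An `ltr_config` supplying `evalue_grid`, `length_grid`,
#'   `count_grid`.
#' @param dedup_extensional Drop single-child generals from the test
#'   vocabulary (default TRUE; FALSE enumerates redundant duplicates).
#' @param pair_repetition Allow `BEFORE(d, d)` pairs (default TRUE).
#' @return `data.frame` of class `ltr_tests`, one row per test, in canonical
#'   order (family, then domain/grid indices); carries the enumeration
#'   configuration as attributes.
#' @export
enumerate_tests <- function(hierarchy, cfg,
                            dedup_extensional = TRUE,
                            pair_repetition = TRUE) {
  doms <- if (dedup_extensional) hierarchy$test_domains
          else c(hierarchy$subdomains, hierarchy$generals)
  E <- cfg$evalue_grid
  L <- cfg$length_grid
  K <- length(E)
  nd <- length(doms)

  occ <- if (K) expand.grid(ek = seq_len(K), d1 = seq_len(nd),
                            KEEP.OUT.ATTRS = FALSE) else
           data.frame(ek = integer(0), d1 = integer(0))
  occ <- data.frame(variant = rep("OCCURS", nrow(occ)),
                    d1 = occ$d1, d2 = rep(NA_integer_, nrow(occ)),
                    ek = occ$ek,
                    len_dir = rep(NA_character_, nrow(occ)),
                    len_limit = rep(NA_integer_, nrow(occ)),
                    count_thr = rep(NA_integer_, nrow(occ)),
                    stringsAsFactors = FALSE)

  ol <- if (K && length(L))
    expand.grid(li = seq_along(L), dir = c("min", "max"), ek = seq_len(K),
                d1 = seq_len(nd), KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE) else
    data.frame(li = integer(0), dir = character(0), ek = integer(0),
               d1 = integer(0))
  ol <- data.frame(variant = rep("OCCURS_LEN", nrow(ol)),
                   d1 = ol$d1, d2 = rep(NA_integer_, nrow(ol)), ek = ol$ek,
                   len_dir = as.character(ol$dir), len_limit = L[ol$li],
                   count_thr = rep(NA_integer_, nrow(ol)),
                   stringsAsFactors = FALSE)

  bf <- if (K) expand.grid(ek = seq_len(K), d2 = seq_len(nd),
                           d1 = seq_len(nd), KEEP.OUT.ATTRS = FALSE) else
          data.frame(ek = integer(0), d2 = integer(0), d1 = integer(0))
  if (!pair_repetition && nrow(bf)) bf <- bf[bf$d1 != bf$d2, , drop = FALSE]
  bf <- data.frame(variant = rep("BEFORE", nrow(bf)),
                   d1 = bf$d1, d2 = bf$d2, ek = bf$ek,
                   len_dir = rep(NA_character_, nrow(bf)),
                   len_limit = rep(NA_integer_, nrow(bf)),
                   count_thr = rep(NA_integer_, nrow(bf)),
                   stringsAsFactors = FALSE)

  ct <- expand.grid(thr = cfg$count_grid, g = seq_along(hierarchy$generals),
                    KEEP.OUT.ATTRS = FALSE)
  ct <- data.frame(variant = rep("COUNT", nrow(ct)),
                   d1 = rep(NA_integer_, nrow(ct)),
                   d2 = rep(NA_integer_, nrow(ct)),
                   ek = rep(NA_integer_, nrow(ct)),
                   len_dir = rep(NA_character_, nrow(ct)),
                   len_limit = rep(NA_integer_, nrow(ct)),
                   count_thr = ct$thr, gidx = ct$g, stringsAsFactors = FALSE)
  occ$gidx <- rep(NA_integer_, nrow(occ))
  ol$gidx <- rep(NA_integer_, nrow(ol))
  bf$gidx <- rep(NA_integer_, nrow(bf))

  tests <- rbind(occ, ol, bf, ct)
  rownames(tests) <- NULL
  tests$domain <- ifelse(is.na(tests$d1), hierarchy$generals[tests$gidx],
                         doms[tests$d1])
  tests$domain2 <- ifelse(is.na(tests$d2), NA_character_, doms[tests$d2])
  tests$evalue <- ifelse(is.na(tests$ek), NA_real_, E[tests$ek])
  structure(tests, class = c("ltr_tests", "data.frame"),
            test_domains = doms,
            evalue_grid = E,
            dedup_extensional = dedup_extensional,
            pair_repetition = pair_repetition)
}

#' Human-readable rendering of node tests
#' @param tests `ltr_tests` rows.
#' @return Character vector.
#' @export
format_tests <- function(tests) {
  out <- character(nrow(tests))
  v <- tests$variant
  out[v == "OCCURS"] <- sprintf("occurs(%s, e<=%g)",
                                tests$domain[v == "OCCURS"],
                                tests$evalue[v == "OCCURS"])
  i <- v == "OCCURS_LEN"
  out[i] <- sprintf("occurs(%s, e<=%g, length %s %d)", tests$domain[i],
                    tests$evalue[i],
                    ifelse(tests$len_dir[i] == "min", ">=", "<="),
                    tests$len_limit[i])
  i <- v == "BEFORE"
  out[i] <- sprintf("before(%s, %s, e<=%g)", tests$domain[i],
                    tests$domain2[i], tests$evalue[i])
  i <- v == "COUNT"
  out[i] <- sprintf("count(%s) > %d", tests$domain[i], tests$count_thr[i])
  out
}

# ---------------------------------------------------------------------------
# Feature cache: per-example sufficient statistics that make every node test
# O(1) to evaluate. For each (test domain d, e-value grid index k) we keep,
# over the qualifying hits (subsumed by d, evalue <= grid[k]):
#   existence, max/min hit length, min/max oriented start.
# Orientation: hits of a minus-strand example are reversed (ostart = -end)
# so precedence reads in element order on either strand.
# ---------------------------------------------------------------------------

#' Build the evaluation cache for a set of examples or candidates
#'
#' @param ids Character vector of example/candidate identifiers (row order of
#'   the cache).
#' @param hits Hit `data.frame` (`source_seq`, `subject_id`, `start`, `end`,
#'   `strand`, `evalue`); `source_seq` values must be in `ids`.
#' @param hierarchy An `ltr_hierarchy`.
#' @param cfg An `ltr_config` (e-value grid).
#' @param test_domains Test-domain vocabulary; defaults to the hierarchy's
#'   deduplicated one and must match the enumeration used.
#' @return Opaque `ltr_cache` object.
#' @export
build_feature_cache <- function(ids, hits, hierarchy, cfg,
                                test_domains = hierarchy$test_domains) {
  stray <- setdiff(unique(hits$source_seq), ids)
  if (length(stray))
    stop("hits reference unknown example id(s): ",
         paste(utils::head(stray, 5L), collapse = ", "))
  n <- length(ids)
  D <- length(test_domains)
  K <- length(cfg$evalue_grid)
  G <- length(hierarchy$generals)
  nc <- D * K
  EXI <- matrix(FALSE, n, nc)
  MAXLEN <- matrix(-Inf, n, nc); MINLEN <- matrix(Inf, n, nc)
  MINSTART <- matrix(Inf, n, nc); MAXSTART <- matrix(-Inf, n, nc)
  CNT <- matrix(0L, n, G)

  if (nrow(hits) && K) {
    ex <- match(hits$source_seq, ids)
    sub <- hits$subject_id
    len <- hits$end - hits$start + 1L
    ostart <- ifelse(hits$strand == "-", -hits$end, hits$start)
    k0 <- findInterval(hits$evalue, cfg$evalue_grid, left.open = TRUE) + 1L
    gi <- match(unname(hierarchy$parent[sub]), hierarchy$generals)
    cnt_dt <- data.table::data.table(ex = ex, gi = gi)[, .N, by = c("ex", "gi")]
    CNT[cbind(cnt_dt$ex, cnt_dt$gi)] <- cnt_dt$N

    own <- match(sub, test_domains)
    gen <- match(unname(hierarchy$parent[sub]), test_domains)
    dt <- data.table::data.table(
      ex = c(ex, ex), d = c(own, gen), k0 = c(k0, k0),
      len = c(len, len), ostart = c(ostart, ostart))
    dt <- dt[!is.na(dt$d) & dt$k0 <= K, ]
    if (nrow(dt)) {
      agg <- dt[, list(maxlen = max(len), minlen = min(len),
                       minstart = min(ostart), maxstart = max(ostart)),
                by = c("ex", "d", "k0")]
      idx <- cbind(agg$ex, (agg$d - 1L) * K + agg$k0)
      MAXLEN[idx] <- agg$maxlen; MINLEN[idx] <- agg$minlen
      MINSTART[idx] <- agg$minstart; MAXSTART[idx] <- agg$maxstart
      # accumulate across the e-value grid: a hit qualifying at k qualifies
      # at every k' > k
      for (d in if (K >= 2L) seq_len(D) else integer(0)) {
        base <- (d - 1L) * K
        for (k in 2:K) {
          a <- base + k; b <- base + k - 1L
          MAXLEN[, a] <- pmax(MAXLEN[, a], MAXLEN[, b])
          MINLEN[, a] <- pmin(MINLEN[, a], MINLEN[, b])
          MINSTART[, a] <- pmin(MINSTART[, a], MINSTART[, b])
          MAXSTART[, a] <- pmax(MAXSTART[, a], MAXSTART[, b])
        }
      }
      EXI <- MAXLEN > -Inf
    }
  }
  structure(list(ids = ids, K = K, D = D,
                 EXI = EXI, MAXLEN = MAXLEN, MINLEN = MINLEN,
                 MINSTART = MINSTART, MAXSTART = MAXSTART, CNT = CNT,
                 test_domains = test_domains),
            class = "ltr_cache")
}

# evaluate one enumerated test (row of an ltr_tests table) on cache rows
eval_test_cached <- function(cache, test, rows = seq_along(cache$ids)) {
  K <- cache$K
  switch(test$variant,
    OCCURS = {
      cache$EXI[rows, (test$d1 - 1L) * K + test$ek]
    },
    OCCURS_LEN = {
      col <- (test$d1 - 1L) * K + test$ek
      if (test$len_dir == "min") cache$MAXLEN[rows, col] >= test$len_limit
      else cache$MINLEN[rows, col] <= test$len_limit
    },
    BEFORE = {
      c1 <- (test$d1 - 1L) * K + test$ek
      c2 <- (test$d2 - 1L) * K + test$ek
      cache$MINSTART[rows, c1] < cache$MAXSTART[rows, c2]
    },
    COUNT = {
      cache$CNT[rows, test$gidx] > test$count_thr
    },
    stop("unknown test variant: ", test$variant))
}

# evaluate many tests -> logical matrix length(rows) x nrow(tests)
eval_tests_cached <- function(cache, tests, rows = seq_along(cache$ids)) {
  out <- matrix(FALSE, length(rows), nrow(tests))
  for (j in seq_len(nrow(tests)))
    out[, j] <- eval_test_cached(cache, tests[j, ], rows)
  out
}

#' Evaluate relational tests on candidates
#'
#' @param candidates An `ltr_candidates` set (see [candidate_set()]) or a
#'   training-example set.
#' @param tests One or more rows of an [enumerate_tests()] table.
#' @param hierarchy An `ltr_hierarchy`.
#' @param cfg An `ltr_config`; its `evalue_grid` must be the grid the tests
#'   were enumerated with.
#' @return Logical matrix, candidates in rows, tests in columns.
#' @export
evaluate_tests <- function(candidates, tests, hierarchy, cfg) {
  stopifnot(inherits(tests, "data.frame"))
  cache <- build_feature_cache(candidates$ids, candidates$hits, hierarchy, cfg,
                               test_domains = attr(tests, "test_domains") %||%
                                 hierarchy$test_domains)
  m <- eval_tests_cached(cache, tests)
  dimnames(m) <- list(candidates$ids, NULL)
  m
}

#' @rdname evaluate_tests
#' @param candidate A single-candidate set.
#' @param test A single test row.
#' @return `evaluate_test`: logical scalar (or vector over candidates).
#' @export
evaluate_test <- function(candidate, test, hierarchy,
                          cfg = run_config()) {
  drop(evaluate_tests(candidate, test, hierarchy, cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
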