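# Independent naive oracles. These deliberately use plain double loops over
# hits (no caching, no vectorisation) so they share no code path with the
# package's evaluator or learner.

# oracle for a single test on one candidate's hits
oracle_eval <- function(hits, variant, domain, domain2, evalue, len_dir,
                        len_limit, count_thr, hierarchy = HIER) {
  n <- nrow(hits)
  if (variant == "COUNT") {
    cnt <- 0L
    for (i in seq_len(n))
      if (unname(hierarchy$parent[hits$subject_id[i]]) == domain)
        cnt <- cnt + 1L
    return(cnt > count_thr)
  }
  sub_ok <- function(q, s) q == s || unname(hierarchy$parent[s]) == q
  okey <- if (n && hits$strand[1L] == "-") -hits$end else hits$start
  if (variant == "OCCURS") {
    for (i in seq_len(n))
      if (hits$evalue[i] <= evalue && sub_ok(domain, hits$subject_id[i]))
        return(TRUE)
    return(FALSE)
  }
  if (variant == "OCCURS_LEN") {
    for (i in seq_len(n)) {
      len <- hits$end[i] - hits$start[i] + 1L
      if (hits$evalue[i] <= evalue && sub_ok(domain, hits$subject_id[i]) &&
          (if (len_dir == "min") len >= len_limit else len <= len_limit))
        return(TRUE)
    }
    return(FALSE)
  }
  if (variant == "BEFORE") {
    for (i in seq_len(n)) {
      if (hits$evalue[i] > evalue || !sub_ok(domain, hits$subject_id[i]))
        next
      for (j in seq_len(n)) {
        if (j == i) next
        if (hits$evalue[j] <= evalue && sub_ok(domain2, hits$subject_id[j]) &&
            okey[i] < okey[j])
          return(TRUE)
      }
    }
    return(FALSE)
  }
  stop("unknown variant ", variant)
}

# oracle evaluation of a whole test table on one candidate's hits
oracle_eval_all <- function(hits, tests, hierarchy = HIER) {
  out <- logical(nrow(tests))
  v <- tests$variant; d <- tests$domain; d2 <- tests$domain2
  e <- tests$evalue; ld <- tests$len_dir; ll <- tests$len_limit
  ct <- tests$count_thr
  for (j in seq_len(nrow(tests)))
    out[j] <- oracle_eval(hits, v[j], d[j], d2[j], e[j], ld[j], ll[j], ct[j],
                          hierarchy)
  out
}

oracle_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

# exhaustive split scoring: returns index of the gain-optimal valid test
# (first in canonical order), or NA if no valid split with positive gain
oracle_best_split <- function(hits_by_id, y, tests, min_leaf,
                              hierarchy = HIER) {
  n <- length(y)
  M <- matrix(FALSE, n, nrow(tests))
  for (i in seq_len(n))
    M[i, ] <- oracle_eval_all(hits_by_id[[i]], tests, hierarchy)
  best <- NA_integer_; best_gain <- 0
  h0 <- oracle_entropy(sum(y) / n)
  for (j in seq_len(nrow(tests))) {
    nyes <- sum(M[, j]); nno <- n - nyes
    if (nyes < min_leaf || nno < min_leaf) next
    pyes <- sum(y & M[, j]); pno <- sum(y) - pyes
    gain <- h0 - (nyes / n) * oracle_entropy(pyes / nyes) -
      (nno / n) * oracle_entropy(pno / nno)
    if (gain > best_gain + 1e-12) { best <- j; best_gain <- gain }
  }
  list(best = best, gain = best_gain)
}
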