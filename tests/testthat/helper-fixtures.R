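# Shared fixture builders. Everything is generated in code; no binary data.

HIER <- ltr_hierarchy()
CFG <- run_config()
TESTS <- enumerate_tests(HIER, CFG)

# quick hit-table builder (1-based inclusive coordinates)
mk_hits <- function(source_seq, subject_id, start, end, strand = "+",
                    evalue = 1e-20) {
  data.frame(source_seq = source_seq, subject_id = subject_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, evalue = evalue, stringsAsFactors = FALSE)
}

# single unvalidated candidate wrapped as an example set
mk_cand <- function(hits, id = unique(hits$source_seq)) {
  example_set(id, hits)
}

# pick one enumerated test by fields (errors if not exactly one row)
pick_test <- function(variant, domain, evalue = NULL, domain2 = NULL,
                      len_dir = NULL, len_limit = NULL, count_thr = NULL) {
  sel <- TESTS$variant == variant & TESTS$domain == domain
  if (!is.null(evalue)) sel <- sel & TESTS$evalue == evalue
  if (!is.null(domain2)) sel <- sel & TESTS$domain2 == domain2
  if (!is.null(len_dir)) sel <- sel & TESTS$len_dir == len_dir
  if (!is.null(len_limit)) sel <- sel & TESTS$len_limit == len_limit
  if (!is.null(count_thr)) sel <- sel & TESTS$count_thr == count_thr
  sel[is.na(sel)] <- FALSE
  stopifnot(sum(sel) == 1L)
  TESTS[which(sel), , drop = FALSE]
}

# random single-strand fuzz candidate with <= max_hits hits
fuzz_candidate <- function(id, max_hits = 10L) {
  n <- sample.int(max_hits, 1L)
  strand <- sample(c("+", "-"), 1L)
  start <- sort(sample.int(8000L, n))
  len <- sample(20:700, n, replace = TRUE)
  mk_hits(id, sample(HIER$subdomains, n, replace = TRUE),
          start, start + len - 1L, strand,
          10^runif(n, -60, 0))
}

# deterministic architectures (degenerate ranges) for layout-controlled
# genome fixtures: element length is exactly 2 * flank + sum(gaps + lens)
fixed_arch <- function(sf, subdomains, lens, gap = 150L, flank = 250L) {
  architecture_spec(sf, data.frame(
    subdomain = subdomains, len_min = lens, len_max = lens,
    log10e_min = -30, log10e_max = -30, stringsAsFactors = FALSE),
    gap_range = c(gap, gap), flank_range = c(flank, flank),
    dropout = 0, spurious_rate = 0)
}

fixed_architectures <- function() {
  list(
    Copia = fixed_arch("Copia",
      c("Retrotrans_gag", "retropepsin_like_LTR_1", "rve", "RT_LTR",
        "RNase_HI_RT_Ty1"), c(300L, 250L, 350L, 550L, 300L)),
    Gypsy = fixed_arch("Gypsy",
      c("Retrotran_gag_2", "retropepsin_like_LTR_2", "RT_LTR",
        "RNase_HI_RT_Ty3", "rve"), c(300L, 250L, 550L, 300L, 350L)),
    `Bel-Pao` = fixed_arch("Bel-Pao",
      c("DUF1759", "Peptidase_A17", "RT_pepA17", "RNase_HI_like", "rve"),
      c(300L, 250L, 550L, 300L, 350L)))
}

# tiny labelled corpus built by hand: n_a sequences of superfamily a etc.,
# each with one diagnostic hit
mk_corpus <- function(n_a = 5L, n_b = 5L, a = "Copia", b = "Gypsy") {
  ids_a <- sprintf("a%03d", seq_len(n_a))
  ids_b <- sprintf("b%03d", seq_len(n_b))
  hits <- rbind(
    mk_hits(rep(ids_a, each = 1L), "RNase_HI_RT_Ty1", 100, 400),
    mk_hits(rep(ids_b, each = 1L), "RNase_HI_RT_Ty3", 100, 400))
  list(hits = hits,
       labels = setNames(c(rep(a, n_a), rep(b, n_b)), c(ids_a, ids_b)))
}
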