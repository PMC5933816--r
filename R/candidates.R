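#' Sliding windows over a genome sequence
#'
#' Windows of `cfg$window_length` nt advance by
#' `window_length - window_overlap` so consecutive windows share exactly
#' `window_overlap` nt; the final window is truncated at the sequence end and
#' windows stop as soon as the sequence end is covered. Coordinates are
#' 1-based inclusive.
#'
#' @param genome Named character vector of sequences (see [read_fasta()]), or
#'   a named integer vector of sequence lengths.
#' @param cfg An `ltr_config`.
#' @return `data.frame` with columns `seq_id`, `start`, `end`.
#' @export
window_genome <- function(genome, cfg) {
  lens <- if (is.character(genome)) nchar(genome) else as.integer(genome)
  ids <- names(genome)
  stopifnot(!is.null(ids))
  step <- cfg$window_length - cfg$window_overlap
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    len <- lens[[i]]
    if (len < 1L) { out[[i]] <- NULL; next }
    starts <- 1L
    while (utils::tail(starts, 1L) + cfg$window_length - 1L < len)
      starts <- c(starts, utils::tail(starts, 1L) + step)
    out[[i]] <- data.frame(seq_id = ids[i], start = starts,
                           end = pmin(starts + cfg$window_length - 1L, len),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assign genome-coordinate hits to the windows that fully contain them
#'
#' A hit in the overlap of two windows is assigned to both (as the domain
#' scanner, run per window, would report it twice). A hit not fully contained
#' in any window is a consistency error: it is longer than the window overlap
#' and straddles a window boundary.
#'
#' @param windows Output of [window_genome()].
#' @param hits Genome-coordinate hit `data.frame`.
#' @return `hits` with an added integer `window` column (row index into
#'   `windows`), one row per (hit, containing window).
#' @export
assign_hits_to_windows <- function(windows, hits) {
  if (!nrow(hits))
    return(cbind(hits, window = integer(0)))
  res <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    w <- which(windows$seq_id == hits$source_seq[i] &
               windows$start <= hits$start[i] &
               windows$end >= hits$end[i])
    if (!length(w))
      stop("consistency error: hit ", hits$subject_id[i], " at ",
           hits$source_seq[i], ":", hits$start[i], "-", hits$end[i],
           " is not contained in any window")
    res[[i]] <- cbind(hits[rep(i, length(w)), , drop = FALSE],
                      window = w)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Candidate container
#'
#' A candidate set couples a candidate table (one row per candidate region)
#' with the domain hits each candidate carries. Invariants checked: every
#' candidate has at least one hit, all its hits lie on one strand (the
#' candidate's), and its boundaries equal its first/last hit positions.
#'
#' @param table `data.frame` with columns `candidate_id`, `seq_id`, `start`,
#'   `end`, `strand`.
#' @param hits Hit `data.frame` whose `source_seq` values are candidate ids.
#' @param validate Check the invariants (default TRUE).
#' @return Object of class `ltr_candidates`: list with `ids`, `table`,
#'   `hits`.
#' @export
candidate_set <- function(table, hits, validate = TRUE) {
  if (validate && nrow(table)) {
    for (i in seq_len(nrow(table))) {
      h <- hits[hits$source_seq == table$candidate_id[i], , drop = FALSE]
      if (!nrow(h))
        stop("candidate ", table$candidate_id[i], " has no hits")
      if (length(unique(h$strand)) != 1L || h$strand[1L] != table$strand[i])
        stop("candidate ", table$candidate_id[i], " violates strand purity")
      if (min(h$start) != table$start[i] || max(h$end) != table$end[i])
        stop("candidate ", table$candidate_id[i],
             " boundaries not trimmed to its hits")
    }
  }
  structure(list(ids = table$candidate_id, table = table, hits = hits),
            class = "ltr_candidates")
}

#' @export
print.ltr_candidates <- function(x, ...) {
  cat("ltr_candidates:", nrow(x$table), "candidates,", nrow(x$hits), "hits\n")
  invisible(x)
}

#' Build candidate regions from windows and domain hits
#'
#' Implements the boundary-estimation rules: (i) hits seen by two overlapping
#' windows are de-duplicated (key: subject, coordinates, strand);
#' (ii) consecutive windows sharing a hit that intersects their overlap
#' region are merged, transitively; (iii) each merged region is split by
#' strand into one candidate per strand; (iv) candidate boundaries are
#' trimmed to the first/last hit; (v) hit-free windows yield no candidate.
#' Warns if any single hit is at least as long as the window overlap (the
#' merge rule assumes domains shorter than the overlap).
#'
#' @param windows Output of [window_genome()].
#' @param hits Genome-coordinate hit `data.frame` (no `window` column needed;
#'   assignment is performed internally).
#' @param cfg An `ltr_config`.
#' @return An `ltr_candidates` set; candidate ids encode the window span and
#'   strand (`<seq>:w<first>-w<last>:<+/->`).
#' @export
build_candidates <- function(windows, hits, cfg) {
  empty <- candidate_set(
    data.frame(candidate_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE), empty_hits())
  if (!nrow(hits) || !nrow(windows)) return(empty)
  if (any(hits$end - hits$start + 1L >= cfg$window_overlap))
    warning("hit(s) as long as the window overlap (", cfg$window_overlap,
            " nt): the window-merge rule may miss boundary-straddling domains")
  ah <- assign_hits_to_windows(windows, hits)
  occupied <- sort(unique(ah$window))
  if (!length(occupied)) return(empty)

  # group consecutive windows joined by a hit in their shared overlap
  group <- integer(nrow(windows)); gid <- 0L
  for (w in occupied) group[w] <- 0L
  ord <- order(windows$seq_id, windows$start)
  pos_in_ord <- match(seq_len(nrow(windows)), ord)
  for (w in occupied) {
    merged_back <- FALSE
    p <- pos_in_ord[w]
    if (p > 1L) {
      prev <- ord[p - 1L]
      if (group[prev] > 0L &&
          windows$seq_id[prev] == windows$seq_id[w] &&
          windows$start[w] <= windows$end[prev]) {
        ov_s <- windows$start[w]; ov_e <- windows$end[prev]
        pool <- ah[ah$window %in% c(prev, w), , drop = FALSE]
        if (any(pool$start <= ov_e & pool$end >= ov_s)) {
          group[w] <- group[prev]
          merged_back <- TRUE
        }
      }
    }
    if (!merged_back) { gid <- gid + 1L; group[w] <- gid }
  }

  tabs <- list(); hlist <- list()
  for (g in seq_len(gid)) {
    ws <- which(group == g)
    gh <- ah[ah$window %in% ws, , drop = FALSE]
    key <- paste(gh$subject_id, gh$start, gh$end, gh$strand, sep = "\r")
    gh <- gh[!duplicated(key), , drop = FALSE]
    seq_id <- windows$seq_id[ws[1L]]
    wfirst <- min(ws); wlast <- max(ws)
    for (s in intersect(c("+", "-"), unique(gh$strand))) {
      sh <- gh[gh$strand == s, , drop = FALSE]
      cid <- sprintf("%s:w%d-w%d:%s", seq_id, wfirst, wlast, s)
      sh$source_seq <- cid
      sh$window <- NULL
      tabs[[length(tabs) + 1L]] <- data.frame(
        candidate_id = cid, seq_id = seq_id,
        start = min(sh$start), end = max(sh$end), strand = s,
        stringsAsFactors = FALSE)
      hlist[[length(hlist) + 1L]] <- sh
    }
  }
  table <- do.call(rbind, tabs); rownames(table) <- NULL
  chits <- do.call(rbind, hlist); rownames(chits) <- NULL
  o <- order(table$seq_id, table$start, table$strand)
  candidate_set(table[o, , drop = FALSE], chits)
}
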