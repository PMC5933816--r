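#' Read a tabular domain-hit report
#'
#' Reads RPS-Blast-style tabular output with the fixed dialect
#' `query_id  subject_id  q_start  q_end  strand  evalue` (tab-separated, no
#' header, `#` comment lines ignored). A BLAST-like 5-column dialect without
#' the strand column is also accepted; there, as in rpsblast's tabular
#' output, a minus-strand match is reported with `q_start > q_end`.
#' Coordinates are normalised so `start <= end`, recording the strand.
#'
#' @param path Hit table file.
#' @param hierarchy `ltr_hierarchy`; rows whose `subject_id` does not resolve
#'   in the vocabulary raise an error listing the identifiers.
#' @return `data.frame` with columns `source_seq`, `subject_id`, `start`,
#'   `end`, `strand`, `evalue` (1-based inclusive coordinates).
#' @export
read_domain_hits <- function(path, hierarchy) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#",
                           colClasses = "character", fill = FALSE)
  if (ncol(raw) == 5L) {
    names(raw) <- c("source_seq", "subject_id", "start", "end", "evalue")
    raw$strand <- NA_character_
  } else if (ncol(raw) == 6L) {
    names(raw) <- c("source_seq", "subject_id", "start", "end", "strand",
                    "evalue")
  } else {
    stop("hit table format error: expected 5 or 6 tab-separated columns, got ",
         ncol(raw))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  if (anyNA(start) || anyNA(end))
    stop("hit table format error: non-integer coordinate at row ",
         which(is.na(start) | is.na(end))[1L])
  evalue <- suppressWarnings(as.numeric(raw$evalue))
  if (anyNA(evalue))
    stop("hit table format error: non-numeric evalue at row ",
         which(is.na(evalue))[1L], " ('", raw$evalue[which(is.na(evalue))[1L]],
         "')")
  if (any(evalue < 0))
    stop("hit table format error: negative evalue at row ",
         which(evalue < 0)[1L])
  bad <- setdiff(unique(raw$subject_id), hierarchy$subdomains)
  if (length(bad))
    stop("unknown subject_id(s) not in the domain vocabulary: ",
         paste(bad, collapse = ", "))
  rev <- start > end
  strand <- raw$strand
  strand[is.na(strand) | !nzchar(strand)] <- ifelse(rev[is.na(strand) | !nzchar(strand)], "-", "+")
  if (!all(strand %in% c("+", "-")))
    stop("hit table format error: strand must be '+' or '-'")
  hits <- data.frame(source_seq = raw$source_seq,
                     subject_id = raw$subject_id,
                     start = ifelse(rev, end, start),
                     end = ifelse(rev, start, end),
                     strand = strand,
                     evalue = evalue,
                     stringsAsFactors = FALSE)
  hits
}

#' Write a domain-hit table in the package dialect
#'
#' @param hits Hit `data.frame` as returned by [read_domain_hits()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  stopifnot(all(c("source_seq", "subject_id", "start", "end", "strand",
                  "evalue") %in% names(hits)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(hits))
    writeLines(paste(hits$source_seq, hits$subject_id, hits$start, hits$end,
                     hits$strand, format(hits$evalue, scientific = TRUE,
                                         digits = 6, trim = TRUE),
                     sep = "\t"), con, sep = "\n")
  invisible(path)
}

empty_hits <- function() {
  data.frame(source_seq = character(0), subject_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Read a label map (sequence id to superfamily)
#'
#' Two-column tab-separated file: `seq_id  superfamily`.
#' @param path File path.
#' @return Named character vector keyed by sequence id.
#' @export
read_label_map <- function(path) {
  m <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "#")
  if (ncol(m) != 2L) stop("label map must have 2 tab-separated columns")
  bad <- setdiff(unique(m[[2L]]), superfamilies())
  if (length(bad))
    stop("unknown superfamily label(s): ", paste(bad, collapse = ", "))
  stats::setNames(m[[2L]], m[[1L]])
}

#' @rdname read_label_map
#' @param labels Named character vector.
#' @export
write_label_map <- function(labels, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(labels))
    writeLines(paste(names(labels), unname(labels), sep = "\t"), con, sep = "\n")
  invisible(path)
}
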