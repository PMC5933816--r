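#' Read a FASTA file of genome or element sequences
#'
#' Minimal strict FASTA reader. Residues are uppercased; record order is
#' preserved. Malformed input (residue data before the first header, an
#' empty header, an empty record, characters outside `A,C,G,T,N`) raises a
#' format error naming the offending line.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the first
#'   whitespace-delimited token of each header), class `ltr_genome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("FASTA format error: empty file: ", path)
  is_header <- startsWith(lines, ">")
  first_content <- which(nzchar(trimws(lines)))[1L]
  if (!is_header[first_content])
    stop("FASTA format error at line ", first_content,
         ": residue data before any header")
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_chunks <- character(0); cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_id)) return()
    s <- toupper(paste(cur_chunks, collapse = ""))
    if (!nzchar(s))
      stop("FASTA format error at line ", cur_line,
           ": empty record '", cur_id, "'")
    bad <- regmatches(s, regexpr("[^ACGTN]", s))
    if (length(bad) && nzchar(bad))
      stop("FASTA format error in record '", cur_id,
           "': invalid residue '", bad, "'")
    ids <<- c(ids, cur_id); seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      cur_id <- strsplit(trimws(substring(ln, 2L)), "[ \t]+")[[1L]][1L]
      if (is.na(cur_id) || !nzchar(cur_id))
        stop("FASTA format error at line ", i, ": empty header")
      cur_chunks <- character(0); cur_line <- i
    } else {
      cur_chunks <- c(cur_chunks, gsub("[ \t]", "", ln))
    }
  }
  flush()
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(seqs, ids), class = "ltr_genome")
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "wb")  # binary: byte-stable across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}
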