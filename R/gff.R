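#' Write superfamily predictions as GFF3
#'
#' One feature line per prediction, 1-based inclusive coordinates, sorted by
#' (seq_id, start, end, superfamily) for byte-stable output. Attributes carry
#' `ID`, `Superfamily` and `Probability` (4 decimal places).
#'
#' @param preds `data.frame` with columns `candidate_id`, `seq_id`, `start`,
#'   `end`, `strand`, `label`, `prob`.
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_predictions_gff <- function(preds, path, source = "ltrforest") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(preds)) {
    o <- order(preds$seq_id, preds$start, preds$end, preds$label)
    p <- preds[o, , drop = FALSE]
    writeLines(paste(p$seq_id, source, "LTR_retrotransposon",
                     p$start, p$end,
                     sprintf("%.4f", p$prob), p$strand, ".",
                     sprintf("ID=%s;Superfamily=%s;Probability=%.4f",
                             p$candidate_id, p$label, p$prob),
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read annotations or predictions from GFF3
#'
#' Understands the package's own prediction output and plain reference
#' annotation GFF3 where the superfamily is carried in a `Superfamily=` (or
#' `Name=`) attribute.
#'
#' @param path GFF3 file.
#' @return `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `label` and, when present, `prob` and `id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      label = character(0), prob = numeric(0),
                      id = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 9L))
    stop("GFF3 format error: expected 9 columns at line ", which(nc != 9L)[1L])
  m <- do.call(rbind, parts)
  attr_field <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    got <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    out[got] <- sub(paste0("^(;)?", key, "="), "", sub("^;", "", hit))
    out
  }
  label <- attr_field(m[, 9L], "Superfamily")
  label[is.na(label)] <- attr_field(m[, 9L], "Name")[is.na(label)]
  prob <- suppressWarnings(as.numeric(attr_field(m[, 9L], "Probability")))
  start <- as.integer(m[, 4L]); end <- as.integer(m[, 5L])
  if (anyNA(start) || anyNA(end) || any(end < start))
    stop("GFF3 format error: bad coordinates")
  data.frame(seq_id = m[, 1L], start = start, end = end,
             strand = m[, 7L], label = label, prob = prob,
             id = attr_field(m[, 9L], "ID"), stringsAsFactors = FALSE)
}

#' Write reference annotations as GFF3
#'
#' @param annotations `data.frame` with `seq_id`, `start`, `end`, `strand`,
#'   `label`.
#' @param path Output file.
#' @param source GFF3 source column value.
#' @return `path`, invisibly.
#' @export
write_annotations_gff <- function(annotations, path, source = "ltrforest_sim") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  if (nrow(annotations)) {
    o <- order(annotations$seq_id, annotations$start, annotations$end)
    a <- annotations[o, , drop = FALSE]
    ids <- if (!is.null(a$id)) a$id else sprintf("ann%04d", seq_len(nrow(a)))
    writeLines(paste(a$seq_id, source, "LTR_retrotransposon",
                     a$start, a$end, ".", a$strand, ".",
                     sprintf("ID=%s;Superfamily=%s", ids, a$label),
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}
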