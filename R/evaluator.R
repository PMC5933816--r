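#' Overlap/containment matching of predictions against annotations
#'
#' A prediction is a true positive iff some annotation with the same
#' superfamily label on the same sequence overlaps it by at least
#' `min_overlap` nucleotides, or either interval contains the other
#' completely (overlap length in 1-based inclusive terms:
#' `min(ends) - max(starts) + 1`). Strand is ignored. Every annotation counts
#' once toward recall no matter how many predictions hit it.
#'
#' @param predictions `data.frame` with `seq_id`, `start`, `end`, `label`.
#' @param annotations `data.frame` with `seq_id`, `start`, `end`, `label` and
#'   optionally `id` (generated when absent).
#' @param min_overlap Minimum overlap in nt (default 100).
#' @return List of class `ltr_match`: `pred_tp` (logical per prediction),
#'   `pred_matches` (list of matched annotation ids), `ann_ids`, `ann_found`
#'   (logical per annotation).
#' @export
match_annotations <- function(predictions, annotations, min_overlap = 100L) {
  ann_ids <- if (!is.null(annotations$id) && !anyNA(annotations$id))
    annotations$id else sprintf("ann%05d", seq_len(nrow(annotations)))
  if (anyDuplicated(ann_ids)) stop("annotation ids must be unique")
  np <- nrow(predictions)
  pred_tp <- logical(np)
  pred_matches <- vector("list", np)
  ann_found <- logical(nrow(annotations))
  for (i in seq_len(np)) {
    cand <- which(annotations$seq_id == predictions$seq_id[i] &
                  annotations$label == predictions$label[i])
    if (!length(cand)) next
    ov <- pmin(annotations$end[cand], predictions$end[i]) -
          pmax(annotations$start[cand], predictions$start[i]) + 1L
    contain <- (predictions$start[i] <= annotations$start[cand] &
                predictions$end[i] >= annotations$end[cand]) |
               (annotations$start[cand] <= predictions$start[i] &
                annotations$end[cand] >= predictions$end[i])
    hit <- cand[ov >= min_overlap | contain]
    if (length(hit)) {
      pred_tp[i] <- TRUE
      pred_matches[[i]] <- ann_ids[hit]
      ann_found[hit] <- TRUE
    }
  }
  structure(list(pred_tp = pred_tp, pred_matches = pred_matches,
                 ann_ids = ann_ids, ann_found = ann_found),
            class = "ltr_match")
}

#' Precision-recall curve over the probability threshold
#'
#' One point per distinct predicted probability, swept from high to low. At
#' threshold `t`, the positive set is the predictions with probability
#' `>= t`; precision is the fraction of those that are true positives under
#' the overlap/containment rule, recall the fraction of annotations matched
#' by at least one of them.
#'
#' @param predictions `data.frame` with `seq_id`, `start`, `end`, `label`,
#'   `prob`.
#' @param annotations Annotation `data.frame` (same superfamily as the
#'   predictions' labels for a single-superfamily curve).
#' @param min_overlap Minimum overlap in nt.
#' @return `data.frame` of class `ltr_pr` with columns `threshold`,
#'   `precision`, `recall`, `f1`; attribute `annotation_total`.
#' @export
pr_curve <- function(predictions, annotations, min_overlap = 100L) {
  if (!nrow(annotations))
    stop("recall undefined: zero annotations")
  m <- match_annotations(predictions, annotations, min_overlap)
  # best probability of any prediction matching each annotation
  ann_best <- rep(-Inf, nrow(annotations))
  for (i in seq_len(nrow(predictions))) {
    if (m$pred_tp[i]) {
      j <- match(m$pred_matches[[i]], m$ann_ids)
      ann_best[j] <- pmax(ann_best[j], predictions$prob[i])
    }
  }
  thresholds <- sort(unique(predictions$prob), decreasing = TRUE)
  pts <- lapply(thresholds, function(t) {
    sel <- predictions$prob >= t
    data.frame(threshold = t,
               precision = sum(m$pred_tp & sel) / sum(sel),
               recall = sum(ann_best >= t) / nrow(annotations))
  })
  curve <- do.call(rbind, pts)
  if (is.null(curve))
    curve <- data.frame(threshold = numeric(0), precision = numeric(0),
                        recall = numeric(0))
  curve$f1 <- ifelse(curve$precision + curve$recall > 0,
                     2 * curve$precision * curve$recall /
                       (curve$precision + curve$recall), 0)
  structure(curve, class = c("ltr_pr", "data.frame"),
            annotation_total = nrow(annotations))
}

#' Maximal F1 along a PR curve
#'
#' @param curve An `ltr_pr` curve (or any data.frame with `precision` and
#'   `recall`).
#' @return Largest harmonic mean of precision and recall over the points
#'   (F1 = 0 where precision + recall = 0).
#' @export
max_f1 <- function(curve) {
  if (!nrow(curve)) stop("empty PR curve")
  p <- curve$precision; r <- curve$recall
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  max(f1)
}

#' Combined multi-superfamily PR curve with a None category
#'
#' The abstention threshold is swept over the distinct best-superfamily
#' probabilities. At threshold `t`, predictions whose best probability is
#' `>= t` are labelled with their argmax superfamily, the rest are None.
#' Precision's denominator is the non-None predictions; a prediction is
#' correct iff it matches an annotation of its predicted superfamily.
#' Recall's denominator is all annotations of all superfamilies. Thresholds
#' where every prediction is None (empty precision denominator) are omitted.
#'
#' @param records Output of [score_candidates()] (per-superfamily probability
#'   columns).
#' @param annotations Annotations across all superfamilies.
#' @param min_overlap Minimum overlap in nt.
#' @return An `ltr_pr` data.frame.
#' @export
combined_pr <- function(records, annotations, min_overlap = 100L) {
  if (!nrow(annotations)) stop("recall undefined: zero annotations")
  labelled <- combine_predictions(records, none_threshold = 0)
  m <- match_annotations(labelled, annotations, min_overlap)
  ann_best <- rep(-Inf, nrow(annotations))
  for (i in seq_len(nrow(labelled))) {
    if (m$pred_tp[i]) {
      j <- match(m$pred_matches[[i]], m$ann_ids)
      ann_best[j] <- pmax(ann_best[j], labelled$prob[i])
    }
  }
  thresholds <- sort(unique(labelled$prob), decreasing = TRUE)
  pts <- lapply(thresholds, function(t) {
    sel <- labelled$prob >= t          # the non-None set at this threshold
    if (!sum(sel)) return(NULL)
    data.frame(threshold = t,
               precision = sum(m$pred_tp & sel) / sum(sel),
               recall = sum(ann_best >= t) / nrow(annotations))
  })
  curve <- do.call(rbind, pts)
  if (is.null(curve))
    curve <- data.frame(threshold = numeric(0), precision = numeric(0),
                        recall = numeric(0))
  curve$f1 <- ifelse(curve$precision + curve$recall > 0,
                     2 * curve$precision * curve$recall /
                       (curve$precision + curve$recall), 0)
  structure(curve, class = c("ltr_pr", "data.frame"),
            annotation_total = nrow(annotations))
}

#' Exclusive-find comparison of two methods
#'
#' Partitions the annotations found by two match results computed against the
#' same annotation set.
#'
#' @param matches_a,matches_b `ltr_match` results over the same annotations.
#' @return Named integer vector `c(only_a, both, only_b)`.
#' @export
exclusive_comparison <- function(matches_a, matches_b) {
  if (!identical(matches_a$ann_ids, matches_b$ann_ids))
    stop("consistency error: match results cover different annotation sets")
  a <- matches_a$ann_found; b <- matches_b$ann_found
  c(only_a = sum(a & !b), both = sum(a & b), only_b = sum(!a & b))
}

#' Write a PR curve as a tab-separated table
#'
#' @param curve `ltr_pr`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pr_table <- function(curve, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("threshold\tprecision\trecall\tf1",
               sprintf("%.6g\t%.6g\t%.6g\t%.6g", curve$threshold,
                       curve$precision, curve$recall, curve$f1)),
             con, sep = "\n")
  invisible(path)
}
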