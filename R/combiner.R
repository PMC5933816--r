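#' Score candidates with per-superfamily forests
#'
#' @param candidates `ltr_candidates`.
#' @param forests Named list of `ltr_forest`s keyed by superfamily; all must
#'   share the same vocabulary and enumeration configuration.
#' @param hierarchy `ltr_hierarchy`.
#' @return `data.frame` (one row per candidate) with the candidate table
#'   columns plus one probability column per superfamily (named as the
#'   superfamily).
#' @export
score_candidates <- function(candidates, forests, hierarchy) {
  if (is.null(names(forests)) || any(!nzchar(names(forests))))
    stop("configuration error: forests must be a named list keyed by superfamily")
  bad <- setdiff(names(forests), superfamilies())
  if (length(bad))
    stop("configuration error: unknown superfamily forest(s): ",
         paste(bad, collapse = ", "))
  keys <- vapply(forests, function(f)
    paste(f$n_tests, f$params$dedup_extensional, f$params$pair_repetition),
    character(1L))
  if (length(unique(keys)) > 1L)
    stop("configuration error: forests use different test vocabularies")
  rec <- candidates$table
  for (sf in names(forests)) {
    p <- if (nrow(rec)) unname(predict_proba(forests[[sf]], candidates,
                                             hierarchy)) else numeric(0)
    rec[[sf]] <- p
  }
  rec
}

#' Combine per-superfamily probabilities into one label
#'
#' Picks the superfamily with the highest probability if it strictly exceeds
#' `none_threshold`, otherwise `None`. Exact ties break by the fixed order
#' Copia, Gypsy, Bel-Pao.
#'
#' @param records Output of [score_candidates()] (or any `data.frame` with
#'   probability columns named by superfamily).
#' @param none_threshold Abstention threshold in `[0, 1]`.
#' @return `records` with added columns `label` and `prob` (the winning
#'   probability, reported even when the label is None).
#' @export
combine_predictions <- function(records, none_threshold = 0.5) {
  sfs <- intersect(superfamilies(), names(records))
  if (!length(sfs)) stop("no superfamily probability columns present")
  pm <- as.matrix(records[, sfs, drop = FALSE])
  if (nrow(pm)) {
    best <- apply(pm, 1L, which.max)   # first max = fixed-order tie-break
    maxp <- pm[cbind(seq_len(nrow(pm)), best)]
    records$label <- ifelse(maxp > none_threshold, sfs[best], "None")
    records$prob <- maxp
  } else {
    records$label <- character(0)
    records$prob <- numeric(0)
  }
  records
}

#' Key-domain baseline classifier
#'
#' Predicts membership of `target` from the mere presence of its key
#' subdomain (any e-value): RNase_HI_RT_Ty1 for Copia, RNase_HI_RT_Ty3 for
#' Gypsy, RT_pepA17 for Bel-Pao.
#'
#' @param candidates `ltr_candidates`.
#' @param target Superfamily.
#' @return Named logical vector over candidates.
#' @export
baseline_predict <- function(candidates, target) {
  key <- key_domains()[target]
  if (is.na(key))
    stop("configuration error: unknown superfamily '", target, "'")
  has <- tapply(candidates$hits$subject_id == key,
                factor(candidates$hits$source_seq, levels = candidates$ids),
                any, default = FALSE)
  stats::setNames(as.logical(has), candidates$ids)
}
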