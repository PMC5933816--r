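#' Save a relational forest as versioned, human-readable JSON
#'
#' Leaf probabilities are stored as integer counts (`n`, `pos`) so that a
#' saved and reloaded forest predicts bit-for-bit identically. Internal nodes
#' store the canonical test index plus a human-readable rendering; the frozen
#' enumeration configuration travels in `params`, so the test table is
#' reconstructed exactly on load.
#'
#' @param forest `ltr_forest`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(forest, path) {
  stopifnot(inherits(forest, "ltr_forest"))
  hierarchy <- ltr_hierarchy()
  tests <- forest_tests(forest, hierarchy)
  ser_node <- function(node) {
    if (node$leaf) list(n = node$n, pos = node$pos)
    else list(test = node$test,
              repr = format_tests(tests[node$test, , drop = FALSE]),
              yes = ser_node(node$yes), no = ser_node(node$no))
  }
  obj <- list(format = forest$format, version = forest$version,
              target = forest$target, params = forest$params,
              n_tests = forest$n_tests,
              trees = lapply(forest$trees, ser_node))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the restored `ltr_forest`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("model file parse error in ", path, ": ",
                         conditionMessage(e)))
  if (!identical(obj$format, "ltrforest-model"))
    stop("not an ltrforest model file: ", path)
  if (!identical(as.integer(obj$version), 1L))
    stop("incompatible model file version ", obj$version,
         " (this build reads version 1)")
  de_node <- function(node) {
    if (!is.null(node$test))
      list(leaf = FALSE, test = as.integer(node$test),
           yes = de_node(node$yes), no = de_node(node$no))
    else list(leaf = TRUE, n = as.integer(node$n), pos = as.integer(node$pos))
  }
  p <- obj$params
  structure(list(
    format = obj$format, version = 1L, target = obj$target,
    params = list(evalue_grid = as.numeric(unlist(p$evalue_grid)),
                  length_grid = as.integer(unlist(p$length_grid)),
                  count_grid = as.integer(unlist(p$count_grid)),
                  min_leaf = as.integer(p$min_leaf),
                  n_trees = as.integer(p$n_trees),
                  seed = as.integer(p$seed),
                  bootstrap = isTRUE(p$bootstrap),
                  sample_features = isTRUE(p$sample_features),
                  dedup_extensional = isTRUE(p$dedup_extensional),
                  pair_repetition = isTRUE(p$pair_repetition),
                  split_criterion = p$split_criterion,
                  aggregation = p$aggregation),
    n_tests = as.integer(obj$n_tests),
    trees = lapply(obj$trees, de_node),
    inbag = NULL
  ), class = "ltr_forest")
}
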