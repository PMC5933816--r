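#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline. Defaults are the published
#' settings: 10 kb sliding windows overlapping by 1 kb, the 8-value
#' significance grid and 6-value length grid of the node-test language,
#' occurrence-count thresholds 1..5 on general domains, 100-tree forests
#' with a minimum of 5 training examples per leaf, and a 0.5 abstention
#' (None) threshold for combined predictions.
#'
#' @param window_length Sliding-window length in nucleotides.
#' @param window_overlap Overlap between consecutive windows, nucleotides;
#'   must be smaller than `window_length`.
#' @param evalue_grid Ascending vector of e-value ceilings available to node
#'   tests.
#' @param length_grid Ascending vector of length limits (nt) for
#'   occurrence-with-length tests; each limit is used both as a minimum and
#'   as a maximum bound.
#' @param count_grid Integer thresholds for "more than k occurrences of a
#'   general domain" tests.
#' @param n_trees Number of trees per forest.
#' @param min_leaf Minimum number of training examples in a leaf.
#' @param none_threshold Probability that the best superfamily must exceed
#'   for a combined prediction to be emitted (otherwise None).
#' @param rng_seed Integer seed controlling all randomised steps.
#' @return An object of class `ltr_config` (a validated list).
#' @export
run_config <- function(window_length = 10000L,
                       window_overlap = 1000L,
                       evalue_grid = c(1e-50, 1e-40, 1e-30, 1e-20,
                                       1e-10, 1e-05, 1e-02, 1e-01),
                       length_grid = c(20L, 50L, 100L, 200L, 500L, 700L),
                       count_grid = 1:5,
                       n_trees = 100L,
                       min_leaf = 5L,
                       none_threshold = 0.5,
                       rng_seed = 1L) {
  cfg <- list(window_length = as.integer(window_length),
              window_overlap = as.integer(window_overlap),
              evalue_grid = as.numeric(evalue_grid),
              length_grid = as.integer(length_grid),
              count_grid = as.integer(count_grid),
              n_trees = as.integer(n_trees),
              min_leaf = as.integer(min_leaf),
              none_threshold = as.numeric(none_threshold),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "ltr_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$window_length > 0L,
            cfg$window_overlap >= 0L,
            cfg$window_overlap < cfg$window_length,
            cfg$min_leaf >= 1L,
            cfg$n_trees >= 1L,
            cfg$none_threshold >= 0, cfg$none_threshold <= 1)
  for (g in list(cfg$evalue_grid, cfg$length_grid, cfg$count_grid)) {
    if (length(g) && is.unsorted(g, strictly = TRUE))
      stop("configuration grids must be strictly sorted ascending")
  }
  invisible(cfg)
}

#' @export
print.ltr_config <- function(x, ...) {
  cat("ltrforest run configuration\n")
  cat(sprintf("  window %d nt, overlap %d nt\n", x$window_length, x$window_overlap))
  cat("  e-value grid:", paste(format(x$evalue_grid), collapse = " "), "\n")
  cat("  length grid:", paste(x$length_grid, collapse = " "), "\n")
  cat("  count thresholds:", paste(x$count_grid, collapse = " "), "\n")
  cat(sprintf("  forest: %d trees, min leaf %d; none threshold %.2f; seed %d\n",
              x$n_trees, x$min_leaf, x$none_threshold, x$rng_seed))
  invisible(x)
}

#' Canonical superfamily vocabulary
#'
#' Fixed order used everywhere a deterministic tie-break over superfamilies
#' is needed.
#' @return Character vector `c("Copia", "Gypsy", "Bel-Pao")`.
#' @export
superfamilies <- function() c("Copia", "Gypsy", "Bel-Pao")

#' Key diagnostic subdomain of each superfamily (baseline model)
#'
#' The baseline classifier predicts a superfamily from the mere presence of
#' one key subdomain: RNase_HI_RT_Ty1 for Copia, RNase_HI_RT_Ty3 for Gypsy
#' and RT_pepA17 for Bel-Pao.
#' @return Named character vector keyed by superfamily.
#' @export
key_domains <- function() {
  c(Copia = "RNase_HI_RT_Ty1", Gypsy = "RNase_HI_RT_Ty3",
    `Bel-Pao` = "RT_pepA17")
}
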