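#' Architecture specification for a simulated superfamily
#'
#' Describes the domain architecture the generator plants: an ordered list of
#' subdomains with length and e-value ranges, inter-domain gap range, LTR-like
#' flank range (included in the annotated element but carrying no hits, so
#' candidate boundaries — which never include the LTRs — are strictly inside
#' the annotation), per-domain dropout and a spurious-hit rate.
#'
#' @param superfamily Label from [superfamilies()].
#' @param domains `data.frame` with columns `subdomain`, `len_min`, `len_max`
#'   (hit length range, nt), `log10e_min`, `log10e_max` (e-value
#'   log10-uniform range).
#' @param gap_range Inter-domain gap range (nt).
#' @param flank_range LTR-like flank length range on each side (nt).
#' @param strand_prob Probability a genomic insertion lands on the plus
#'   strand.
#' @param dropout Per-domain probability of being missed by the scanner.
#' @param spurious_rate Expected spurious (weak, e-value >= 1e-3) hits per kb
#'   of element.
#' @return Object of class `ltr_architecture`.
#' @export
architecture_spec <- function(superfamily, domains,
                              gap_range = c(50L, 400L),
                              flank_range = c(150L, 350L),
                              strand_prob = 0.5,
                              dropout = 0.1,
                              spurious_rate = 0.05) {
  stopifnot(superfamily %in% superfamilies(),
            all(c("subdomain", "len_min", "len_max",
                  "log10e_min", "log10e_max") %in% names(domains)),
            dropout >= 0, dropout <= 1, strand_prob >= 0, strand_prob <= 1,
            spurious_rate >= 0, all(domains$len_min >= 1),
            all(domains$len_max >= domains$len_min))
  structure(list(superfamily = superfamily, domains = domains,
                 gap_range = as.integer(gap_range),
                 flank_range = as.integer(flank_range),
                 strand_prob = strand_prob, dropout = dropout,
                 spurious_rate = spurious_rate),
            class = "ltr_architecture")
}

arch_domains <- function(subdomains, len_min, len_max) {
  data.frame(subdomain = subdomains, len_min = len_min, len_max = len_max,
             log10e_min = -50, log10e_max = -10, stringsAsFactors = FALSE)
}

#' Default simulated architectures for the three superfamilies
#'
#' Copia carries Integrase before RT; Gypsy and Bel-Pao share the
#' RT-before-Integrase order and are distinguished by their subdomain
#' identities (diagnostic RNase/AP/RT subtypes), mirroring the real
#' structural contrast between the superfamilies. All planted hit lengths
#' stay below 800 nt so no domain can outgrow the window overlap.
#'
#' @param dropout Per-domain dropout probability (default 0.1).
#' @param spurious_rate Spurious hits per kb of element (default 0.05).
#' @param strand_prob Plus-strand probability for genomic insertions.
#' @return Named list of `ltr_architecture` (Copia, Gypsy, Bel-Pao).
#' @export
default_architectures <- function(dropout = 0.1, spurious_rate = 0.05,
                                  strand_prob = 0.5) {
  mk <- function(sf, doms)
    architecture_spec(sf, doms, dropout = dropout,
                      spurious_rate = spurious_rate,
                      strand_prob = strand_prob)
  list(
    Copia = mk("Copia", arch_domains(
      c("Retrotrans_gag", "retropepsin_like_LTR_1", "rve", "RT_LTR",
        "RNase_HI_RT_Ty1"),
      c(250L, 200L, 300L, 450L, 250L), c(400L, 350L, 450L, 700L, 400L))),
    Gypsy = mk("Gypsy", arch_domains(
      c("Retrotran_gag_2", "retropepsin_like_LTR_2", "RT_LTR",
        "RNase_HI_RT_Ty3", "rve"),
      c(250L, 200L, 450L, 250L, 300L), c(400L, 350L, 700L, 400L, 450L))),
    `Bel-Pao` = mk("Bel-Pao", arch_domains(
      c("DUF1759", "Peptidase_A17", "RT_pepA17", "RNase_HI_like", "rve"),
      c(250L, 200L, 450L, 250L, 300L), c(400L, 350L, 700L, 400L, 450L)))
  )
}

#' Two-class domain-order recovery task
#'
#' Both classes carry the same five subdomains; the second class presents
#' them in exactly reversed order, so identity features are uninformative and
#' only precedence (and position-correlated) structure separates the classes.
#' Used by the parameter-recovery experiments.
#'
#' @inheritParams default_architectures
#' @return Named list of two `ltr_architecture`s (labelled Copia and Gypsy).
#' @export
order_task_architectures <- function(dropout = 0.1, spurious_rate = 0.05) {
  doms <- c("Retrotrans_gag", "retropepsin_like", "rve", "RT_LTR",
            "RNase_HI_like")
  lmin <- c(250L, 200L, 300L, 450L, 250L)
  lmax <- c(400L, 350L, 450L, 700L, 400L)
  list(
    Copia = architecture_spec("Copia", arch_domains(doms, lmin, lmax),
                              dropout = dropout,
                              spurious_rate = spurious_rate),
    Gypsy = architecture_spec("Gypsy",
                              arch_domains(rev(doms), rev(lmin), rev(lmax)),
                              dropout = dropout,
                              spurious_rate = spurious_rate))
}

rint <- function(n, lo, hi) {
  if (lo == hi) rep(as.integer(lo), n) else
    as.integer(lo + floor(stats::runif(n) * (hi - lo + 1L)))
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# one element in its own (plus-strand, local) orientation
realize_element <- function(spec, zero_noise = FALSE) {
  d <- spec$domains
  keep <- if (zero_noise || spec$dropout == 0) rep(TRUE, nrow(d)) else
    stats::runif(nrow(d)) > spec$dropout
  flank5 <- rint(1L, spec$flank_range[1L], spec$flank_range[2L])
  flank3 <- rint(1L, spec$flank_range[1L], spec$flank_range[2L])
  pos <- flank5
  hits <- list()
  for (i in seq_len(nrow(d))) {
    gap <- rint(1L, spec$gap_range[1L], spec$gap_range[2L])
    len <- rint(1L, d$len_min[i], d$len_max[i])
    start <- pos + gap
    if (keep[i]) {
      ev <- 10^stats::runif(1L, d$log10e_min[i], d$log10e_max[i])
      hits[[length(hits) + 1L]] <- data.frame(
        subject_id = d$subdomain[i], start = start, end = start + len - 1L,
        evalue = ev, stringsAsFactors = FALSE)
    }
    pos <- start + len - 1L
  }
  total <- pos + flank3
  hdf <- if (length(hits)) do.call(rbind, hits) else
    data.frame(subject_id = character(0), start = integer(0),
               end = integer(0), evalue = numeric(0), stringsAsFactors = FALSE)
  # weak spurious hits anywhere inside the element
  if (!zero_noise && spec$spurious_rate > 0) {
    ns <- stats::rpois(1L, spec$spurious_rate * total / 1000)
    if (ns > 0L) {
      hierarchy <- ltr_hierarchy()
      slen <- rint(ns, 30L, 150L)
      sstart <- rint(ns, 1L, max(1L, total - max(slen)))
      hdf <- rbind(hdf, data.frame(
        subject_id = sample(hierarchy$subdomains, ns, replace = TRUE),
        start = sstart, end = sstart + slen - 1L,
        evalue = 10^stats::runif(ns, -3, -0.5), stringsAsFactors = FALSE))
    }
  }
  list(length = total, hits = hdf)
}

#' Simulate a Repbase-like labelled training corpus
#'
#' Each sequence is one element realised from its superfamily's architecture;
#' the class-defining signal is the identity and order of its domain hits.
#' Per-domain dropout removes hits; spurious hits add weak noise. A fraction
#' `minus_prob` of sequences is stored in minus-strand orientation (hits
#' reverse-ordered, strand `-`) and `p_mixed` sequences get an extra
#' opposite-strand hit (these are removed by the training-assembly filters).
#' Deterministic under `seed`.
#'
#' @param specs Named list of `ltr_architecture`s.
#' @param n_per_class Sequences per superfamily (>= 1).
#' @param seed Integer seed.
#' @param minus_prob Probability a sequence is presented in minus
#'   orientation.
#' @param p_mixed Probability of injecting an opposite-strand hit.
#' @param out_dir If non-NULL, writes `corpus.fasta`, `corpus_hits.tsv` and
#'   `corpus_labels.tsv` there.
#' @return List with `sequences` (named character), `hits` (hit
#'   `data.frame`), `labels` (named character).
#' @export
simulate_training_corpus <- function(specs, n_per_class, seed = 1L,
                                     minus_prob = 0.1, p_mixed = 0,
                                     out_dir = NULL) {
  if (n_per_class < 1L) stop("parameter error: n_per_class must be >= 1")
  stopifnot(length(specs) >= 1L)
  with_seed(seed, {
    seqs <- character(0); hits <- list(); labels <- character(0)
    for (spec in specs) {
      sf <- spec$superfamily
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s_%05d", gsub("-", "", sf), i)
        el <- realize_element(spec)
        h <- el$hits
        minus <- stats::runif(1L) < minus_prob
        if (nrow(h)) {
          if (minus) {
            s <- el$length - h$end + 1L
            e <- el$length - h$start + 1L
            h$start <- s; h$end <- e
            h$strand <- "-"
          } else h$strand <- "+"
          if (p_mixed > 0 && stats::runif(1L) < p_mixed) {
            h <- rbind(h, data.frame(
              subject_id = h$subject_id[1L], start = 1L,
              end = min(100L, el$length), evalue = 1e-2,
              strand = if (minus) "+" else "-", stringsAsFactors = FALSE))
          }
          h$source_seq <- id
          hits[[length(hits) + 1L]] <-
            h[, c("source_seq", "subject_id", "start", "end", "strand",
                  "evalue")]
        }
        seqs[id] <- rand_seq(el$length)
        labels[id] <- sf
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
    rownames(hits) <- NULL
    out <- list(sequences = structure(seqs, class = "ltr_genome"),
                hits = hits, labels = labels)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(out$sequences, file.path(out_dir, "corpus.fasta"))
      write_domain_hits(out$hits, file.path(out_dir, "corpus_hits.tsv"))
      write_label_map(out$labels, file.path(out_dir, "corpus_labels.tsv"))
    }
    out
  })
}

#' Simulate a genome with planted elements and ground truth
#'
#' Plants realised elements at non-overlapping positions (random, or fixed via
#' `positions`) on either strand in a uniform-background genome. The hit
#' table is expressed in genome coordinates (a minus-strand element's hits
#' are coordinate-reversed with strand `-`), so the candidate builder's
#' merge, de-duplication and strand-split paths are exercised exactly as they
#' would be by a per-window scanner. The truth GFF3 uses the superfamily
#' vocabulary; annotations span the whole element including its hit-free
#' flanks.
#'
#' @param specs Named list of `ltr_architecture`s.
#' @param n_insertions Number of elements to plant.
#' @param genome_length Genome length (nt).
#' @param seed Integer seed.
#' @param positions Optional fixed start positions (length `n_insertions`).
#' @param strands Optional fixed strands.
#' @param classes Optional fixed spec names per insertion.
#' @param background_rate Spurious intergenic hits per kb (default 0).
#' @param zero_noise TRUE disables dropout and all spurious hits.
#' @param seq_id Name of the simulated sequence.
#' @param out_dir If non-NULL, writes `genome.fasta`, `genome_hits.tsv`,
#'   `truth.gff3`.
#' @return List with `genome`, `annotations` (`data.frame` with `id`),
#'   `hits`, `elements`.
#' @export
simulate_genome <- function(specs, n_insertions, genome_length, seed = 1L,
                            positions = NULL, strands = NULL, classes = NULL,
                            background_rate = 0, zero_noise = FALSE,
                            seq_id = "chr_sim", out_dir = NULL) {
  stopifnot(n_insertions >= 1L)
  with_seed(seed, {
    cls <- if (!is.null(classes)) classes else
      sample(names(specs), n_insertions, replace = TRUE)
    stopifnot(all(cls %in% names(specs)))
    els <- lapply(cls, function(cl) realize_element(specs[[cl]], zero_noise))
    lens <- vapply(els, `[[`, integer(1L), "length")
    if (is.null(positions)) {
      free <- genome_length - sum(lens)
      if (free <= n_insertions)
        stop("parameter error: infeasible packing (", sum(lens),
             " nt of elements in a ", genome_length, " nt genome)")
      cuts <- sort(sample.int(free - 1L, n_insertions))
      gaps <- diff(c(0L, cuts))
      positions <- cumsum(gaps) + c(0L, cumsum(lens))[seq_len(n_insertions)] + 1L
    } else {
      o <- order(positions)
      positions <- positions[o]; els <- els[o]; cls <- cls[o]
      lens <- lens[o]
      if (!is.null(strands)) strands <- strands[o]
      ends <- positions + lens - 1L
      if (any(positions < 1L) || any(ends > genome_length) ||
          any(positions[-1L] <= ends[-length(ends)]))
        stop("parameter error: infeasible packing at the given positions")
    }
    strands <- if (!is.null(strands)) strands else
      ifelse(stats::runif(n_insertions) <
               vapply(cls, function(cl) specs[[cl]]$strand_prob, numeric(1L)),
             "+", "-")
    hits <- list(); anns <- list()
    for (i in seq_len(n_insertions)) {
      el <- els[[i]]; p <- positions[i]; L <- el$length
      h <- el$hits
      if (nrow(h)) {
        if (strands[i] == "+") {
          h$start <- p + h$start - 1L
          h$end <- p + h$end - 1L
        } else {
          s <- p + (L - h$end)
          e <- p + (L - h$start)
          h$start <- s; h$end <- e
        }
        h$strand <- strands[i]
        h$source_seq <- seq_id
        hits[[length(hits) + 1L]] <-
          h[, c("source_seq", "subject_id", "start", "end", "strand",
                "evalue")]
      }
      anns[[i]] <- data.frame(seq_id = seq_id, start = p, end = p + L - 1L,
                              strand = strands[i], label = cls[i],
                              id = sprintf("te%03d", i),
                              stringsAsFactors = FALSE)
    }
    if (!zero_noise && background_rate > 0) {
      inter_kb <- (genome_length - sum(lens)) / 1000
      nb <- stats::rpois(1L, background_rate * inter_kb)
      if (nb > 0L) {
        hierarchy <- ltr_hierarchy()
        occ_s <- positions; occ_e <- positions + lens - 1L
        blen <- rint(nb, 30L, 150L)
        bstart <- rint(nb, 1L, genome_length - 200L)
        ok <- vapply(seq_len(nb), function(j)
          !any(bstart[j] <= occ_e + 1L & bstart[j] + blen[j] - 1L >= occ_s - 1L),
          logical(1L))
        if (any(ok)) {
          hits[[length(hits) + 1L]] <- data.frame(
            source_seq = seq_id,
            subject_id = sample(hierarchy$subdomains, sum(ok), replace = TRUE),
            start = bstart[ok], end = bstart[ok] + blen[ok] - 1L,
            strand = sample(c("+", "-"), sum(ok), replace = TRUE),
            evalue = 10^stats::runif(sum(ok), -3, -0.5),
            stringsAsFactors = FALSE)
        }
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
    rownames(hits) <- NULL
    annotations <- do.call(rbind, anns)
    genome <- structure(stats::setNames(rand_seq(genome_length), seq_id),
                        class = "ltr_genome")
    out <- list(genome = genome, annotations = annotations, hits = hits,
                elements = data.frame(class = cls, start = positions,
                                      length = lens, strand = strands,
                                      stringsAsFactors = FALSE))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(out$genome, file.path(out_dir, "genome.fasta"))
      write_domain_hits(out$hits, file.path(out_dir, "genome_hits.tsv"))
      write_annotations_gff(out$annotations, file.path(out_dir, "truth.gff3"))
    }
    out
  })
}
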