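stage_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full identification/classification pipeline
#'
#' Windows the genome, builds candidates from the domain hits (merge,
#' de-duplication, strand split, boundary trim), scores every candidate with
#' each superfamily forest, combines the probabilities under the None rule,
#' and writes the non-None predictions as GFF3 together with a JSON run
#' manifest (configuration snapshot, input digests, per-stage counts).
#'
#' @param genome Path to a FASTA file, or an `ltr_genome`.
#' @param hits Path to a domain-hit table, or a hit `data.frame` in genome
#'   coordinates.
#' @param forests Named list of `ltr_forest`s or model file paths, keyed by
#'   superfamily.
#' @param cfg An `ltr_config`.
#' @param out_gff Output GFF3 path (NULL to skip writing).
#' @param manifest_path Output manifest path (NULL to skip).
#' @param quiet Suppress stage logging to stderr.
#' @return List with `records` (scored, labelled candidate table),
#'   `candidates`, `predictions` (non-None rows), `manifest`.
#' @export
run_pipeline <- function(genome, hits, forests, cfg = run_config(),
                         out_gff = NULL, manifest_path = NULL, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  hierarchy <- ltr_hierarchy()
  input_digests <- list()
  if (is.character(forests))
    forests <- stats::setNames(as.list(forests), names(forests))
  forests <- lapply(forests, function(f) {
    if (inherits(f, "ltr_forest")) return(f)
    if (!file.exists(f))
      stop("configuration error: model file not found: ", f)
    input_digests[[basename(f)]] <<- unname(tools::md5sum(f))
    load_model(f)
  })
  if (!length(forests)) stop("configuration error: no forests supplied")
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    input_digests[["genome"]] <- unname(tools::md5sum(genome))
    genome <- read_fasta(genome)
  }
  if (is.character(hits) && length(hits) == 1L) {
    input_digests[["hits"]] <- unname(tools::md5sum(hits))
    hits <- read_domain_hits(hits, hierarchy)
  }

  windows <- window_genome(genome, cfg)
  stage_log(quiet, "window", "%d windows over %d sequence(s)",
            nrow(windows), length(genome))
  candidates <- build_candidates(windows, hits, cfg)
  stage_log(quiet, "candidates", "%d candidates from %d hits",
            nrow(candidates$table), nrow(hits))
  records <- score_candidates(candidates, forests, hierarchy)
  records <- combine_predictions(records, cfg$none_threshold)
  preds <- records[records$label != "None", , drop = FALSE]
  counts <- table(factor(records$label, levels = c(superfamilies(), "None")))
  stage_log(quiet, "predict", "%s",
            paste(names(counts), as.integer(counts), sep = "=",
                  collapse = " "))
  if (!is.null(out_gff)) {
    write_predictions_gff(preds, out_gff)
    stage_log(quiet, "write", "%d predictions -> %s", nrow(preds), out_gff)
  }
  manifest <- list(
    tool = "ltrforest",
    version = as.character(utils::packageVersion("ltrforest")),
    config = unclass(cfg),
    inputs = input_digests,
    seed = cfg$rng_seed,
    counts = list(sequences = length(genome), windows = nrow(windows),
                  hits = nrow(hits), candidates = nrow(candidates$table),
                  predictions = as.list(counts)),
    mean_candidate_length = if (nrow(candidates$table))
      mean(candidates$table$end - candidates$table$start + 1) else NA,
    output_gff_md5 = if (!is.null(out_gff)) unname(tools::md5sum(out_gff))
                     else NULL,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  if (!is.null(manifest_path)) {
    con <- file(manifest_path, "wb")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), con, sep = "\n")
    close(con)
  }
  list(records = records, candidates = candidates, predictions = preds,
       manifest = manifest)
}

#' Train one forest per superfamily from a labelled corpus
#'
#' @param corpus List with `hits` and `labels` (see
#'   [simulate_training_corpus()] / [read_label_map()]).
#' @param cfg An `ltr_config`.
#' @param targets Superfamilies to train (default: all present in the
#'   corpus labels).
#' @param seed Base seed; forest `i` uses `seed + i - 1`.
#' @param quiet Suppress logging.
#' @return Named list of `ltr_forest`s.
#' @export
train_superfamily_forests <- function(corpus, cfg = run_config(),
                                      targets = NULL, seed = cfg$rng_seed,
                                      quiet = FALSE) {
  hierarchy <- ltr_hierarchy()
  tests <- enumerate_tests(hierarchy, cfg)
  targets <- targets %||% intersect(superfamilies(), unique(corpus$labels))
  forests <- list()
  for (i in seq_along(targets)) {
    sf <- targets[i]
    ex <- assemble_training_set(corpus, sf, seed = seed + i - 1L)
    stage_log(quiet, "train", "%s: %d positives, %d negatives", sf,
              sum(ex$labels), sum(!ex$labels))
    forests[[sf]] <- induce_forest(ex, cfg, hierarchy, target = sf,
                                   seed = seed + i - 1L, tests = tests)
  }
  forests
}

#' Run an external RPS-Blast-style scanner over candidate sequences
#'
#' Optional wrapper around an installed `rpsblast`-compatible executable.
#' `command` is a template with the placeholders `{query}`, `{db}` and
#' `{out}`; the scanner must emit the package's tabular hit dialect (see
#' [read_domain_hits()]). When the executable is missing the function stops
#' with an actionable message: supply a precomputed hit table instead.
#'
#' @param query_fasta Candidate sequences, FASTA.
#' @param db Profile database path handed to the scanner.
#' @param hierarchy `ltr_hierarchy` used to validate the resulting table.
#' @param command Command template; default uses `rpsblast` tabular output.
#' @param out Path for the raw scanner output (temp file by default).
#' @return Hit `data.frame` parsed from the scanner output.
#' @export
run_external_scanner <- function(query_fasta, db,
                                 hierarchy = ltr_hierarchy(),
                                 command = paste(
                                   "rpsblast -query {query} -db {db}",
                                   "-outfmt '6 qseqid sseqid qstart qend",
                                   "evalue' -evalue 0.1 > {out}"),
                                 out = tempfile(fileext = ".tsv")) {
  exe <- strsplit(trimws(command), "[ \t]+")[[1L]][1L]
  if (Sys.which(exe) == "")
    stop("external scanner '", exe, "' not found on PATH; run it elsewhere ",
         "and provide its tabular hit table to read_domain_hits() instead")
  if (!file.exists(query_fasta)) stop("query FASTA not found: ", query_fasta)
  if (!file.size(query_fasta) ||
      !any(startsWith(readLines(query_fasta, warn = FALSE), ">")))
    return(empty_hits())
  cmd <- gsub("{query}", shQuote(query_fasta),
              gsub("{db}", shQuote(db),
                   gsub("{out}", shQuote(out), command, fixed = TRUE),
                   fixed = TRUE), fixed = TRUE)
  status <- system(cmd)
  if (status != 0L)
    stop("external scanner failed (exit ", status, "): ", cmd)
  if (!file.size(out)) return(empty_hits())
  read_domain_hits(out, hierarchy)
}
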