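# ltrforest

Identification and superfamily classification of LTR retrotransposons with
relational random forests.

## What problem this solves, and for whom

Transposable-element annotators need two things at once: *find* the LTR
retrotransposons in an unannotated genome, and *classify* each one into the
Copia, Gypsy or Bel-Pao superfamily. The structural signal that separates the
superfamilies is the identity and order of their conserved protein domains
(GAG, aspartic protease AP, integrase INT, reverse transcriptase RT,
RNase H): Copia carries INT upstream of RT, Gypsy and Bel-Pao carry RT
upstream of INT and differ in their diagnostic subdomain variants. Rule-based
classifiers hard-code a handful of such patterns; `ltrforest` instead *learns*
them from labelled element corpora, and outputs calibrated-ish probabilities
a curator can threshold.

The pipeline:

1. **Window** — sliding windows over the genome (10 kb, 1 kb overlap by
   default).
2. **Delimit** — a candidate spans its first to its last conserved-domain hit
   (RPS-Blast-style tables in, merged across window overlaps, de-duplicated,
   split by strand; hit-free windows are dropped). Boundaries exclude LTRs.
3. **Classify** — one random forest per superfamily whose node tests are
   first-order queries over the candidate's hit set — `occurs(d, e≤·)`, with
   optional length bounds, `before(d1, d2, e≤·)` in element orientation, and
   occurrence counts of general domains — 10,947 tests in all under the
   default vocabulary and grids. Probabilities combine by argmax with a
   *None* abstention below a threshold (default 0.5).

Evaluation follows the standard genome-annotation protocol: a prediction is a
true positive iff it overlaps a same-superfamily annotation by ≥ 100 nt or
either interval contains the other; precision–recall curves sweep the
probability threshold and are summarised by max-F1. A synthetic-data module
generates training corpora and genomes with planted, ground-truthed elements
so the whole pipeline is testable offline. See
`vignettes/ltrforest-methods.Rmd` for the model, its assumptions and the
design decisions.

## Worked example

```r
library(ltrforest)
hierarchy <- ltr_hierarchy()
cfg <- run_config(n_trees = 50)

# 1. a Repbase-like training corpus and per-superfamily forests
specs <- default_architectures(dropout = 0.1)
corpus <- simulate_training_corpus(specs, n_per_class = 150, seed = 42)
forests <- train_superfamily_forests(corpus, cfg, seed = 42)

# 2. a genome with 12 planted elements, scanned hits included
sim <- simulate_genome(specs, n_insertions = 12, genome_length = 400000,
                       seed = 99, background_rate = 0.02)
res <- run_pipeline(sim$genome, sim$hits, forests, cfg,
                    out_gff = "predictions.gff3")

# 3. evaluate against the ground truth
curve <- combined_pr(res$records, sim$annotations)
cat(sprintf("combined max-F1: %.3f\n", max_f1(curve)))
m <- match_annotations(res$predictions, sim$annotations)
cat(sprintf("recall %.2f, precision %.2f at threshold %.1f\n",
            mean(m$ann_found), mean(m$pred_tp), cfg$none_threshold))
```

prints (stage logs on stderr, results on stdout):

```
[train] Copia: 150 positives, 150 negatives
[train] Gypsy: 150 positives, 150 negatives
[train] Bel-Pao: 150 positives, 150 negatives
[window] 45 windows over 1 sequence(s)
[candidates] 19 candidates from 69 hits
[predict] Copia=4 Gypsy=6 Bel-Pao=1 None=8
[write] 11 predictions -> predictions.gff3
combined max-F1: 0.957
recall 0.92, precision 1.00 at threshold 0.5
```

Reading this: 45 windows produced 19 candidates with at least one hit; at the
0.5 abstention threshold 11 were assigned a superfamily and 8 were None
(spurious background hits the forests reject). Every emitted prediction was
correct (precision 1.00); one of the twelve planted elements was missed
(recall 0.92) because dropout removed too much of its domain evidence —
exactly the failure mode the method has on real genomes when a scanner misses
domains. `predictions.gff3` carries one feature per prediction with
`Superfamily=` and `Probability=` attributes.

### Command line

Every stage is a subcommand (`simulate`, `window`, `annotate`, `train`,
`predict`, `evaluate`, `compare`):

```sh
Rscript -e 'ltrforest::ltr_cli()' train --hits corpus_hits.tsv \
    --labels corpus_labels.tsv --n-trees 100 --seed 1 --out-dir models
Rscript -e 'ltrforest::ltr_cli()' predict --genome genome.fasta \
    --hits genome_hits.tsv \
    --models Copia=models/Copia.json,Gypsy=models/Gypsy.json \
    --out predictions.gff3 --manifest manifest.json
```

(or use the wrapper script at `system.file("cli", "ltrforest.R",
package = "ltrforest")`).

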