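---
title: "Methods: relational random forests for LTR retrotransposon annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relational random forests for LTR retrotransposon annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

LTR retrotransposons — the Copia, Gypsy and Bel-Pao superfamilies — encode a
conserved set of protein domains (GAG, aspartic protease, integrase, reverse
transcriptase, RNase H) whose *identity and order* along the element is the
main structural signal separating the superfamilies: Copia elements carry
integrase upstream of RT, while Gypsy and Bel-Pao carry RT upstream of
integrase and differ in their diagnostic subdomain variants. `ltrforest`
turns this observation into a three-step annotation pipeline:

1. **Candidate extraction.** The genome is cut into sliding windows
   (default 10,000 nt, overlapping by 1,000 nt). Windows are cheap and
   deliberately over-generate; later steps discard windows without evidence.
2. **Domain annotation and boundary estimation.** Each window is screened for
   conserved-domain hits (an RPS-Blast-style scanner, or the hit tables this
   package reads and simulates). A candidate spans its first to its last hit.
   Windows sharing a hit that intersects their 1,000-nt overlap are merged
   (transitively, so an element may straddle several windows); a hit seen by
   two overlapping windows is counted once; a merged region with hits on both
   strands is split into one candidate per strand; hit-free windows vanish.
3. **Classification.** One binary random forest per superfamily maps a
   candidate — represented relationally, as its variable-size set of domain
   hits with positions and e-values — to a membership probability. A combined
   prediction takes the superfamily with the highest probability, or **None**
   when no probability strictly exceeds the abstention threshold (default
   0.5).

Because a candidate has a variable number of hits, the trees do not consume a
fixed-length feature vector. Node tests are first-order queries over the hit
set, in four families (all grids configurable, defaults shown):

* *occurrence*: is there a hit of domain `d` with e-value ≤ `e`?
  `e` ranges over {1e-50, 1e-40, 1e-30, 1e-20, 1e-10, 1e-05, 1e-02, 1e-01};
* *occurrence with length bound*: additionally the hit's length
  (`end − start + 1`) is ≥ or ≤ a limit from {20, 50, 100, 200, 500, 700};
* *precedence*: are there qualifying hits of `d1` and `d2` (each with
  e-value ≤ `e`) with the `d1` hit starting strictly before the `d2` hit?
  Other hits may lie in between;
* *count*: does the number of hits under a general domain strictly exceed a
  threshold in 1..5? Count tests take all hits, with no e-value clause.

Domains are drawn from a two-level vocabulary: 26 subdomain profiles (CDD /
Pfam identifiers) grouped under 7 general domains (RNase, Integrase, GAG, AP,
RT, Pre-integrase, YR). Hits name subdomains only; tests may name either
level, with the "is a subdomain of" relation supplied as background
knowledge, so `occurs(RT, …)` accepts an `RT_LTR` hit.

### The size of the test space

The enumeration is complete, canonical and duplicate-free. Two generals
(Integrase, Pre-integrase) have exactly one subdomain each; a test on such a
general is satisfied by exactly the hits that satisfy the test on its
subdomain, so these duplicates are dropped, leaving 31 extensionally distinct
test domains. The resulting space is

| family                | count                | total  |
|-----------------------|----------------------|--------|
| occurrence            | 31 × 8               | 248    |
| occurrence + length   | 31 × 8 × (6 × 2)     | 2,976  |
| precedence            | 31² × 8 (ordered, repetition allowed) | 7,688 |
| count                 | 7 × 5                | 35     |
| **all**               |                      | **10,947** |

Precedence pairs are ordered and allow `d1 = d2` (two hits of the same domain
in order is a satisfiable, occasionally informative pattern). This is the
combination under which the enumerator reproduces the published test-space
size exactly; it is frozen into every model file.

### Strand normalisation

All candidate hits share one strand (the builder guarantees it). For a
minus-strand candidate the element reads right-to-left in genome coordinates,
so precedence is evaluated in *element orientation* (positions reflected).
Without this, a forest trained on element-local corpora would see reversed
domain orders on half the genome.

## The learner

Trees are grown top-down without pruning. At every node a random sample of
⌈√10,947⌉ = 105 tests is scored by information gain (class-entropy
reduction); the best split is installed provided both branches keep at least
`min_leaf = 5` training sequences and the gain is strictly positive,
with ties broken by canonical enumeration order so induction is
deterministic. A node becomes a leaf when pure, smaller than `2 × min_leaf`,
or unsplittable; leaves store raw empirical counts (no Laplace smoothing),
and a forest of 100 trees — each on a bootstrap resample of the training set
(with replacement, to original size) — predicts the *mean* of the leaf
frequencies rather than a majority vote, so the probabilities sweep PR curves
smoothly.

Design points that were genuinely open, and how they were resolved:

* **Split heuristic.** Information gain; the reference systems for
  first-order forests do not document their default. Gain ratio/Gini were
  deliberately not added as defaults. Recorded in the model metadata.
* **Aggregation.** Mean of leaf frequencies, not voting: thresholded voting
  would quantise the PR curves at multiples of 1/`n_trees`.
* **Count tests.** No e-value clause (the e-value qualifier attaches to
  domain-occurrence tests) and strict ">"; this is also the only reading
  consistent with the 10,947 enumeration above.
* **Training sets.** Positives are all target-superfamily sequences that
  survive two filters (at least one hit; hits on a single strand); negatives
  are sampled without replacement from the other superfamilies to the same
  size, or taken in full when fewer exist — the Gypsy-style case, still
  roughly balanced.
* **Abstention tie-break.** At an exact probability tie the combined label
  uses the fixed order Copia, Gypsy, Bel-Pao; ties are measure-zero with
  100-tree averaged probabilities.

The key-domain baseline classifies a candidate as Copia, Gypsy or Bel-Pao
from the mere presence of `RNase_HI_RT_Ty1`, `RNase_HI_RT_Ty3` or
`RT_pepA17` respectively, at any e-value. It is reproducible inside the
forest formalism as a single depth-1 tree testing the key domain at the
loosest e-value — a property the test suite checks.

## Evaluation protocol

Predictions are matched to reference annotations per superfamily, ignoring
strand: a prediction is a true positive iff it overlaps an annotation of the
same superfamily by at least 100 nt, or either interval fully contains the
other (candidate boundaries never include the LTRs, so a correct candidate is
usually *contained in* its annotation). Overlap length is computed 1-based
inclusive: `min(ends) − max(starts) + 1`. Precision is the fraction of
predictions that are true positives; recall the fraction of annotations
matched — each annotation counting once however many predictions hit it. PR
curves sweep the probability threshold over the distinct predicted values;
max-F1 summarises a curve. Unscored methods (the baseline) are a single PR
point at probability 1. For combined predictions, precision's denominator
excludes None predictions and recall's denominator is all annotations; at the
lowest swept threshold nothing is None, and a threshold where *every*
prediction would be None has an empty precision denominator and is omitted
from the curve.

## What the simulator emulates — and what it does not

The generator stands in for the external resources the method normally
consumes (Repbase-style training corpora, genome annotations, a PSSM
database). It emulates the hit-level structure the classifier actually sees:

* per-superfamily domain architectures (subdomain identities, order, length
  ranges, e-values log-uniform in 10⁻⁵⁰..10⁻¹⁰), inter-domain gaps, hit-free
  LTR-like flanks included in the truth annotation;
* per-domain dropout (a scanner missing a domain), weak spurious hits
  (e-value ≥ 10⁻³, so learned e-value thresholds are meaningful), optional
  intergenic background hits;
* genomic placement on both strands, with minus-strand elements presented in
  reversed coordinate order, and layouts that straddle window boundaries.

Planted hit lengths stay below 800 nt, honouring the observation that real
conserved-domain hits are shorter than the 1,000-nt window overlap (the
assumption behind the merge rule; the builder warns when an input violates
it). Background sequence is i.i.d. uniform and hits are *emitted*, not
rediscovered by sequence search: the simulator's contract is hit-level
realism, which keeps every test independent of an external scanner and
database. Consequently a green end-to-end test establishes the correctness
of windowing, merging, strand handling, learning and evaluation — it does
not establish homology-search sensitivity, nor performance on real genomes
where domain decay, nesting and solo LTRs occur.

Default noise levels are fixed once: dropout 0.1 and spurious rate 0.05/kb
(a scanner that misses a tenth of true domains and emits a weak false hit
every ~20 kb of element is a realistic desk-scale regime), strand probability
0.5. The parameter-recovery experiment uses a two-class task whose classes
carry the *same five subdomains in exactly reversed order*, so domain
identity is uninformative and the learner must use precedence structure.
(With only a single repositioned domain, 10% dropout would cap attainable
accuracy at ≈0.95 — whenever the one discriminating domain drops out the
classes are indistinguishable — which would make a ≥0.95 criterion a coin
flip; full reversal keeps every surviving pair informative and the Bayes
ceiling at ≈0.9996.)

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere, matching R/Bioconductor and
  GFF3 conventions; hit tables with `q_start > q_end` are normalised to
  minus-strand hits as RPS-Blast reports them.
* "Minimum e-value" is a significance ceiling: a hit qualifies iff its
  e-value ≤ the test's threshold.
* Leaf probabilities are serialised as integer counts, so a saved model
  reloads bit-for-bit; model files are versioned JSON, never binary.
* Probabilities in GFF3 output are fixed at 4 decimals and records are sorted
  (seq, start) for byte-stable output under a fixed seed.
* Empty inputs degrade explicitly: an empty genome yields no windows; hit-free
  windows yield no candidates; an empty prediction set yields a header-only
  GFF3; PR curves refuse an empty annotation set (recall undefined).
* A leaf forced with zero examples cannot arise from training (leaves hold
  ≥ `min_leaf`); routing defends with p = 0.5 anyway.

## Known limitations

* Candidate boundaries exclude LTRs by construction; downstream users wanting
  full-element coordinates must extend boundaries themselves.
* Mixed-strand merged regions are split into exactly one candidate per
  strand; positional sub-clustering within a strand is not attempted.
* The forest sees only conserved-domain structure: elements whose domains are
  absent or undetected are invisible, which on real genomes caps recall.
* No hierarchical (order → superfamily) classification; each superfamily
  forest is independent and the combiner is a flat argmax with abstention.
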