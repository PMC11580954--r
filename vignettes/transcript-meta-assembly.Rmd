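---
title: "Cell-specific transcript meta-assembly: model and design notes"
author: "txmend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-specific transcript meta-assembly: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmend)
library(data.table)
```

## The problem

Short-read single-cell RNA-seq rarely covers a transcript end to end in any
one cell: dropout and sparse coverage break per-cell assemblies into
*transcript fragments* that end at exon boundaries and miss interior
junctions. The information needed to complete a fragment usually exists —
in another cell. txmend takes one scored assembly per cell (GTF with a
reliability score in [0,1] per transcript), merges fragments across cells
into candidate full-length transcripts, and then decides per cell which
candidates are expressed there, so the output remains cell-specific rather
than a consensus meta-assembly.

Everything operates at the resolution of the *intron chain* — the ordered
list of introns (junctions) of a multi-exon transcript. Two transcripts
are treated as the same model iff their chains are identical on the same
chromosome and strand; terminal exon ends are soft and never compared.
Single-exon transcripts carry no junctions and are excluded throughout.

## The fragment graph

All cells' fragments are pooled. Fragments with identical
(chromosome, strand, chain) collapse into one vertex that remembers every
member (cell, id, score). A directed edge u → v exists iff some non-empty
suffix of u's junction list equals a prefix of v's junction list *and* v
extends strictly beyond u (v's last intron end exceeds u's). Two
consequences worth noting:

* **Acyclicity is structural.** Strict rightward extension plus the merge
  of identical chains means a topological order always exists; the
  dynamic program relies on it and re-verifies it defensively.
* **Containment creates no edge.** A chain that is a strict sub-chain of
  another adds no junctions to any path; contained fragments still
  contribute through compatibility-based scoring.

Graphs are bucketed by (chromosome, strand); unstranded (".") fragments
form their own bucket and never connect to stranded ones.

## Path selection: the merging score

A path p through one weakly-connected component (possibly a single
vertex) represents a candidate transcript whose chain is the union of the
vertex chains along the path. Its objective is

F(p) = BJ(p) · NJ(p),

where NJ(p) is the junction count and BJ(p) the *bottleneck junction
score*: the minimum over junctions j of J(j, p), the summed scores of all
fragments that contain j and are *compatible* with p. A fragment t is
compatible with p when it shares at least one junction with p and no
junction of t that falls inside p's genomic span (first intron start to
last intron end) is absent from p's chain; junctions of t entirely
outside that span are neutral. The bottleneck term demands that every
junction of a candidate be supported — guarding against chimeras — while
the NJ factor rewards extension towards full length.

The search is a per-component dynamic program over the topological order.
At each vertex only the `pn` best paths are retained (default 15), each
extension being **re-scored from scratch against the component's full
fragment pool**: F is not decomposable, because extending a path can
change which fragments are compatible. Per component, at most `pc`
candidates are emitted (default 100) after deduplication by merged chain.

Two design points were genuinely open:

* **Junction scores are pooled across cells during the search.**
  Cell-restricted variants are computed later as features; the search
  itself asks only whether a candidate is well supported somewhere.
* **Emission rule.** Emitting only right-maximal kept paths loses a
  component's best-scoring candidate whenever extension lowers F (the
  bottleneck can only fall as junctions are added). txmend therefore
  suppresses a kept path only when some kept path strictly extends it
  *with an equal or higher merging score*. This still favours full-length
  candidates — a prefix whose extension scores at least as well
  disappears — but makes the heuristic agree exactly with exhaustive
  enumeration on components small enough to enumerate, which the test
  suite verifies on hundreds of random components of up to 8 vertices.

`brute_force_paths()` is that exhaustive oracle: it enumerates every
directed path (refusing components above 15 vertices) and scores each
with the plain interval-based scorer, a code path independent of the
matrix machinery the dynamic program uses.

## Features and the two forests

Candidates are scored in two stages, mirroring how a curator would work:
first "is this transcript real anywhere?", then "is it expressed in this
cell?".

* **30 path-level features** in three groups: junction coverage (five
  summary statistics — min, median, mean, max, population sd — of the
  per-junction scores and of the per-junction compatible-fragment counts,
  plus NJ, BJ, F); cell support (number of supporting cells, statistics
  of per-cell compatible coverage and of per-cell supported-junction
  counts, fraction of supporting cells covering every junction); and
  fragment connectivity (vertex count, a chain-integrity indicator for
  candidates equal to a single input fragment, distinct member cells,
  max/mean member score).
* **21 cell-level features** restricting the same quantities to one cell:
  statistics of cell-restricted junction scores and fragment counts,
  supported-junction count/fraction, the cell-restricted bottleneck,
  total compatible coverage, compatible fragment count and max score,
  membership indicators, the longest consecutive run of supported
  junctions, the cell's coverage rank among supporting cells (normalised
  so the best cell maps to 1 and a sole supporter to 1), and the ratio of
  the cell's coverage to the supporting-cell mean.

A (candidate, cell) pair exists only if the cell expresses at least one
junction of the candidate; mere junction membership suffices for pairing,
compatibility is required only for scoring. Population-sd is used
throughout because the summarised sets are small and determinism matters
more than unbiasedness.

Both models are random forests (100 trees, maximum depth 12, fixed seed
42 by default, single-threaded for reproducibility). The path-level
model is trained on candidates from the training chromosomes (defaults:
1–9, with and without the "chr" prefix), labelled 1 iff the candidate's
chain occurs in the union of all cells' ground truth there. Candidates
scoring below the threshold (default 0.2) are discarded; the pair-level
model is then trained on the surviving pairs with all 51 features,
labelled against each cell's own truth — the filter is also what keeps
that training set reasonably balanced. All scored pairs are emitted with
their probability; a final cutoff is available (`min_score`) but off by
default, leaving the precision/sensitivity trade to the evaluation stage.

## Evaluation semantics

Precision is matching/assembled under exact chain equality. *Adjusted
precision* compares method X to a target sensitivity: X's predictions are
removed one at a time in ascending score order **until the matching count
first equals the target**, and the retained set's precision is reported.
Ties in score are broken by removing the lexicographically larger chain
first — deliberately blind to match status, since removing non-matching
transcripts first would bias the metric upward. Stopping at first
equality makes the identity `adjusted_precision(X, own sensitivity) =
raw precision` hold exactly; an alternative reading (keep removing while
the count stays at the target) reports the most favourable point of the
precision–recall plateau instead, and is intentionally not used. A target
above X's matching count is not comparable and yields `NA`; a target of
zero with no matches removes nothing and reports the raw (zero)
precision.

## What the simulator does and does not emulate

`generate_cells()` builds non-overlapping multi-exon genes (defaults:
4–10 exons of 100–300 bp, introns 200–2000 bp) whose isoforms share a
junction backbone and differ by skipped internal exons or alternative
donor/acceptor boundaries (shifts of 20–80 bp). Each cell expresses each
isoform independently (default probability 0.4). An expressed transcript
survives intact with probability `d_full` (default 0.3); otherwise it is
split at uniformly chosen junction boundaries into pieces of at least two
exons, so fragments end at exon boundaries exactly as assembler outputs
do. Intact transcripts draw scores from Beta(5, 2), fragments from
Beta(2, 5), clamped to [0.05, 1] — reliable-looking full chains, weaker
pieces. With small probability (default 0.02) a fragment also emits a
spurious copy with one junction shifted by 10–50 bp, exercising the
conflict rules.

Splitting discards the boundary junction, so the pieces of one cell never
overlap each other; recovery must combine cells whose split positions
differ by at least two. That is impossible below six exons, which is why
the forced "fragment-only" subset of the recovery scenario (30% of
isoforms, never intact in any cell) is drawn from isoforms with at least
six exons, and why the generator verifies — by an exact reachability
check over the fragments' junction-index intervals — that every
sufficiently expressed isoform remains chainable to full length,
resampling the fragmentation otherwise.

`scenario_recoverable()` fixes the study conditions used by the
acceptance checks: 30 cells, six chromosomes named chr7–chr12 so the
default training set gives a 3+3 chromosome split, 12 genes per
chromosome with 2–4 isoforms (≈200–230 isoforms), `d_full` = 0.25.

The simulator emulates dropout at the intron-chain level only. It does
not model read-level noise, alignment artefacts, soft-clips, expression
magnitude (scores are drawn, not estimated from coverage), intra-exon
truncation, overlapping genes, or correlated expression between cells.
Passing tests therefore demonstrate that the graph, search, features and
models behave as specified under junction-level dropout — not that any
particular accuracy will be attained on real alignments, where score
quality of the upstream assembler dominates.

## Numerical and degenerate-input choices

* Scores are clamped to [0,1] on input; raw coverages above 1 are first
  squashed by x/(x+1) (configurable: min–max or clamp-only).
* Duplicate chains within one cell keep the highest-scoring record.
* Tie-breaks are total and deterministic everywhere: candidates order by
  F, then NJ, then the junction sequence (numerically, via a
  zero-padded key), then the vertex-id sequence; written GTF records
  order by (chrom, start, chain, id). Reruns are byte-identical.
* Empty inputs flow through: empty manifests, cells with no multi-exon
  transcript, and empty components all produce empty, well-formed
  outputs rather than errors; contract violations (a cyclic component, a
  pair violating the pairing rule, schema mismatches between features
  and a model) are hard errors.
* Floating-point comparisons in tests use `testthat`'s default tolerance;
  the merging score itself is exact arithmetic on sums and minima.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data
sized for a single CPU: the recovery scenario above (~2,600 expressed
transcript–cell events, ~5,000 fragments, ~1,000 graph vertices), 200+
random components for the oracle comparison, and 100 random scored sets
for the metric identities. The full suite completes in a few minutes.

## Known limitations

* Chain-level operation cannot repair wrong junctions present in the
  input, only refuse to combine them; an upstream assembler's systematic
  junction errors propagate.
* The candidate set is bounded per component (`pc`); extremely complex
  loci may lose low-scoring isoforms before model scoring.
* Models are retrained per study; no pretrained weights ship with the
  package, and transfer across score distributions of different upstream
  assemblers is untested.
* Single-exon transcripts are out of scope by construction.
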