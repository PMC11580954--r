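# txmend

Cell-specific transcript meta-assembly from fragmented single-cell
assemblies.

Short-read single-cell RNA-seq assemblies are riddled with dropout: in
any one cell, coverage gaps break transcripts into fragments that miss
interior splice junctions, while the missing pieces are usually well
covered in *other* cells. txmend is for people who already have one
assembly per cell (any assembler that emits GTF with a per-transcript
reliability score in [0,1]) and want accurate **per-cell, full-length**
transcript models rather than a consensus meta-assembly.

## Method

txmend works entirely on intron chains (the ordered junctions of a
multi-exon transcript; two models match iff their chains are identical).

1. **Fragment graph.** Fragments from all cells with identical
   (chrom, strand, chain) collapse into one vertex; a directed edge
   u → v exists iff a non-empty suffix of u's junction list equals a
   prefix of v's and v extends strictly rightward. The graph is a DAG by
   construction.
2. **Path search.** Within each connected component a dynamic program
   maximises the merging score

   F(p) = BJ(p) · NJ(p),  BJ(p) = min_{j ∈ p} J(j, p),
   J(j, p) = Σ { score(t) : j ∈ t, t ∼ p },

   where t ∼ p (compatibility) requires t to share a junction with p and
   to carry no junction conflicting with p inside p's span. The DP keeps
   the top `pn` paths per vertex (default 15) and emits at most `pc`
   candidates per component (default 100).
3. **Two random forests** (100 trees, depth 12): a path-level model on
   30 features filters unreliable candidates (threshold 0.2), then a
   pair-level model on all 51 features assigns each surviving
   (candidate, cell) pair a probability Pr(p, c), written per cell as
   the transcript score. Training labels come from exact chain matches
   against ground truth, split by chromosome (train: 1–9 by default).
4. **Evaluation** utilities implement exact intron-chain matching,
   precision, precision–recall curves and adjusted precision (precision
   at a fixed target sensitivity).

A self-contained simulator (`generate_cells()`, `scenario_recoverable()`)
produces reference annotations, per-cell truths and fragmented, scored
per-cell inputs that emulate dropout, so the whole pipeline can be
exercised and validated without any external data.

## Worked example

Three cells each carry one fragment of the same transcript
(chain j1 = 201-299, j2 = 401-499, j3 = 601-699):

```r
library(txmend); library(data.table)

frag <- function(id, chain, score, s, e)
  data.table(id = id, chrom = "chr1", strand = "+",
             tx_start = s, tx_end = e, chain = chain, score = score)

cells <- list(
  make_cell_assembly(frag("t1", "201-299,401-499",         0.8, 100, 550), "cellA"),
  make_cell_assembly(frag("t2", "401-499,601-699",         0.6, 350, 800), "cellB"),
  make_cell_assembly(frag("t3", "201-299,401-499,601-699", 0.4, 120, 790), "cellC"))

build_graph(cells)
#> <fragment_graph> 3 vertices, 2 edges, 1 components, 3 member fragments

assemble_candidates(cells)[, .(candidate_id, chain, nj, bj, f, n_vertices)]
#>    candidate_id                   chain    nj    bj     f n_vertices
#> 1:            1 201-299,401-499,601-699     3     1     3          2
#> 2:            2         401-499,601-699     2     1     2          1

merging_score("201-299,401-499,601-699", fragment_pool(cells))$junction_scores
#> 201-299 401-499 601-699
#>     1.2     1.8     1.0
```

All three fragments are compatible with the full-length path, so its
junction scores are 0.8+0.4 = 1.2, 0.8+0.6+0.4 = 1.8 and 0.6+0.4 = 1.0;
the bottleneck is 1.0, and with three junctions the merging score is
F = 3. The full-length chain — which no single cell contained — is the
top candidate. On real data the candidates then flow through
`build_pair_table()`, `train_models()` and `apply_pipeline()` (or the
`cmd_train` / `cmd_assemble` wrappers, also exposed by the `exec/txmend`
command-line script) to produce per-cell scored GTFs via
`write_cell_gtf()`.

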