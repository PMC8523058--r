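---
title: "Divide-and-conquer alignment by graph clustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer alignment by graph clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmalign)
```

## The problem and the method

Progressive multiple sequence aligners are accurate on hundreds to a few
thousand sequences, but their heuristics scale poorly and their early
mistakes compound on large, divergent datasets. `gcmalign` implements the
divide-and-conquer alternative: break the dataset into subsets, align each
subset independently, and merge the subalignments with a *graph clustering
merge*. The pipeline is:

1. **Guide tree.** A rough phylogeny over the unaligned sequences — by
   default neighbor joining on k-mer cosine distances
   (`build_fallback_tree()`); only a rough tree is needed, since the tree
   is used solely to group similar sequences.
2. **Centroid edge decomposition.** The tree is recursively split by
   deleting the edge that minimizes the larger side's leaf count, until
   every piece has at most `ceiling(n / max_num_subsets)` leaves
   (`centroid_edge_decompose()`). A purely random decomposition is
   available when even a rough tree is too expensive.
3. **Subset alignment.** Each subset is aligned by the base aligner, or —
   when a subset exceeds the recursion threshold — by a nested run of the
   whole pipeline (`should_recurse()`).
4. **Backbones.** Each of `num_backbones` backbone alignments realigns,
   from scratch, an equal-sized random sample of rows from every subset.
   Backbones are the only evidence connecting subsets.
5. **Alignment graph.** Nodes are subalignment columns. Each backbone
   column adds +1 support between the home columns of every pair of
   upper-case residues it aligns (`build_graph()`).
6. **Markov clustering.** The graph is clustered with MCL
   (`mcl_cluster()`): groups of columns that backbones consistently
   co-align become clusters, each destined to be one merged column.
7. **Trace ordering.** Clusters are ordered into a *trace*: a total order
   visiting every subalignment's columns exactly once, in increasing
   order (`order_clusters()`; invariants checked by `validate_trace()`).
8. **Assembly.** One output column per cluster; rows of subalignments
   absent from a cluster receive gaps (`assemble()`).

The merge never re-aligns residues within a subset: within-subset columns
pass through intact, and only their interleaving across subsets is decided
by the graph.

### Why this is correct in the consistent limit

If the subalignments are induced restrictions of one reference alignment
and the backbones are induced restrictions of the same reference covering
every column, then graph components coincide with reference columns, MCL
returns them unchanged (the transition matrix is block diagonal), the
precedence relation is acyclic, and assembly reproduces the reference's
homologous pair set exactly — SP error 0. This limit is the package's
primary end-to-end oracle test; real backbones estimated by a fallible
aligner produce an approximation whose quality the error metrics measure.

## Key parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `max_num_subsets` | 25 | decomposition width; target subset size is `ceiling(n/25)` |
| `num_backbones` | 10 | backbone count; more backbones = denser graph support |
| `backbone_size` | 200 | rows per backbone; 200 is about the practical limit past which accurate aligners slow down sharply, so it bounds each base-aligner call |
| `recursion_threshold` | `max(backbone_size, target_subset_size)` | subsets strictly larger than this are aligned by a nested run; user-overridable |
| MCL `inflation` | 2.0 | standard clustering aggressiveness |
| `gap_open`, `gap_extend` | −4, −1 | built-in aligner affine penalties (match +1/mismatch −1 for nucleotides, BLOSUM62 for proteins) |
| `compress_threshold` | 1e11 bytes (100 GB) | compression engages only above this serialized size |
| k-mer `k` | 5 (nt), 3 (aa) | standard alignment-free practice for rough trees |

Recursion exists for scale, not accuracy: nested runs let the pipeline
handle datasets whose subsets would be too large for any base aligner, but
on datasets that fit, a single-level run is typically at least as
accurate. A recursion depth cap (default 3) turns pathological
configurations into a clear error instead of unbounded nesting; nested
runs derive their seeds from the parent (`child_seed()`), keeping the
whole tree of runs reproducible from one seed.

## Design choices where the design was open

Several parts of the merge admit more than one reasonable realization;
the package's choices, all deterministic, are:

* **Edge weighting.** A backbone column containing `u` upper-case
  residues contributes one unit per residue *pair* (not merely per
  column-pair co-occurrence), so columns matched by many letters get
  proportionally stronger edges. Intra-subalignment pairs are recorded
  too, and resolved later.
* **Cluster validity.** MCL clusters may hold two columns of one
  subalignment; a trace requires at most one. `enforce_cluster_validity()`
  keeps, per offending subalignment, the column with the greatest total
  edge weight into the cluster (ties: lower column index) and evicts the
  rest as singletons.
* **Trace ordering.** Conflicts (cycles in the cluster precedence
  relation) are resolved by a frontier algorithm: a cluster is emitted
  when all of its member columns are the next unemitted column of their
  subalignments (among ready clusters, the one whose smallest
  (subalignment, column) key is least); when no cluster is ready, a cycle
  exists, and the globally smallest frontier node is evicted into a
  singleton cluster, sacrificing only that node's within-cluster pairs.
  This realizes "resolve conflicts with few changes" greedily and
  deterministically; it makes no optimality claim.
* **Backbone quotas.** When `backbone_size` is not divisible by the
  number of subsets, the remainder goes one row each to the first
  subsets; a subset smaller than its quota contributes everything it has.
* **MCL numerics.** Self-loop weight = the node's maximum incident edge
  weight (1 for isolated nodes); entries below 1e-8 are pruned each
  iteration; convergence when the matrix changes by less than 1e-8; a
  1000-iteration cap returns the current interpretation with a warning.
  Clusters are the connected components of the converged matrix's nonzero
  pattern.
* **Centroid tie-break.** Among edges whose deletion yields the same
  larger-side count, the first in postorder is chosen.

## Alignment compression

Very large merged alignments are mostly gaps. `compress_alignment()`
shortens an alignment by *dissolving* columns: every letter of the chosen
column is demoted to lower-case — it thereby stops asserting homology —
and shunted sideways into the nearest gap of its own row. Intervening
lower-case letters are pushed one step further along (a domino); an
upper-case letter blocks a direction, and a residue blocked on both sides
vetoes the whole move. The emptied column is deleted.

Dissolving a column with `u` upper-case letters destroys exactly
`choose(u, 2)` homologous pairs, so columns with at most one upper-case
letter dissolve *losslessly*; `lossless_only = TRUE` restricts the
procedure to those. Candidates are always tried in order of ascending
upper-case count (ties: leftmost), with the candidate list recomputed
after every dissolve — simplest to reason about, and cheap at the rate
columns disappear. The loop stops at the size threshold or when a full
pass finds no valid move; on dense (gap-poor) alignments the second
condition can stop compression well above the requested size, which is
the honest outcome — there is nowhere to shunt letters to.

Size is measured as serialized single-line FASTA bytes
(`estimate_size()`), which equals the written file size. Compressed
output is ordinary FASTA whose lower-case letters mean "present but
unaligned"; the error metrics ignore such letters on both the estimate
and the reference side, so compression can only remove, never fabricate,
homology claims.

## Error metrics

`compare_alignments()` scores an estimate against a reference by
sum-of-pairs: a homologous pair is two residues placed upper-case in the
same column, identified by (sequence id, 0-based ungapped site index) so
that pair sets are invariant under column insertion or deletion. SPFP is
the fraction of estimated pairs not in the reference; SPFN the fraction
of reference pairs not in the estimate; SP error their mean. The estimate
is first restricted to the reference's sequences, so small curated
references score only their own rows. An alignment with no pairs at all
contributes 0 to its rate — a convention, chosen so degenerate inputs
yield defined scores rather than 0/0.

## The synthetic-evolution generator

`simulate_evolution()` provides ground truth: sequences evolve down a
Yule tree with per-site uniform-replacement substitutions
(probability `1 − exp(−rate·bl)` per branch), and Poisson indel events
with geometric lengths (default rate 0.02 per site per unit branch,
mean length 2 — enough to make realistically gappy true alignments
without routinely deleting whole sequences). Site identities persist
through indels, so the true alignment — and hence every derived pair set
— is known exactly; insertions open new columns placed immediately after
their left neighbor in a global column order, which keeps every
lineage's site order consistent with the alignment's column order.

Rather than exposing raw branch lengths, a target expected p-distance can
be given: branch lengths are rescaled so the tree-wide mean of
`(k−1)/k · (1 − exp(−d))` equals the target. Two presets emulate common
regimes: `"16s-like"` (average p-distance ≈ 0.2, a conserved rRNA-like
dataset) and `"rnasim-like"` (≈ 0.4, a divergent simulated-RNA-like
dataset). The generator captures divergence and gappiness, not
substitution-model realism: no rate heterogeneity, no GTR parameters, no
fragmentary sequences. Tests passing on simulated data therefore
demonstrate the *mechanics* of the pipeline (correct bookkeeping, exact
merges in the consistent limit, error strictly better than a no-merge
baseline), not field accuracy on biological data.

## Task runtime and reproducibility

All subset and backbone alignments (and nested runs) are self-contained
tasks in `workdir/tasks/{pending,running,done,failed}`, with deterministic
ids hashed from type and inputs. Claiming a task is an atomic
`file.rename()` into `running/` — on a POSIX filesystem exactly one worker
wins — so any number of processes can share a working directory
(`run_worker()`), and a crashed worker's task is reclaimed after a
timeout. Completed work is never redone: re-invoking `run_pipeline()` on a
finished directory returns the existing output untouched.

During the merge, subalignments are streamed from disk one at a time
through `subalignment_store()`, bounding the merge's footprint by the
largest subalignment rather than their sum; the store counts concurrent
loads, and the test suite asserts the maximum is 1.

Because every random choice flows from the single `seed` through named
`child_seed()` streams recorded in task inputs, the final alignment is
byte-identical across worker counts and across interrupt/resume cycles.

## Problem sizes used by the tests and acceptance script

The automated checks run at desk scale, chosen to exercise every code
path in minutes: the exact-merge oracle at 60 taxa / 4 subsets; twenty
end-to-end runs at 50–200 taxa for conservation and trace validity;
error-vs-baseline comparisons at 200 taxa with 10 subsets and 10
backbones of 50 rows; compression properties on hundreds of random
alignments up to 10×40; MCL equivalence on 50 random graphs of up to 30
nodes. The method itself has no such limits — parameters scale to the
defaults (25 subsets, 200-row backbones) unchanged.

## Known limitations

* The built-in progressive aligner is deliberately simple (k-mer NJ guide
  tree, profile frequencies, affine gaps); production use should plug in
  a stronger external aligner via the adapter, which shifts both subset
  and backbone quality.
* Backbone sampling is uniform; poorly sampled regions get weak graph
  support and fall back to singleton columns (lost cross-subset
  homology).
* The trace heuristic is greedy; no bound on the number of pairs
  sacrificed in cycle breaking is claimed.
* Compression cannot go below the size at which no column admits a valid
  move; it does not perform bit-level compression, and dissolved columns
  are not restorable.
* Multi-process claiming relies on rename atomicity within one
  filesystem; network filesystems without atomic rename are unsupported.
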