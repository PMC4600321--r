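---
title: "Reference-indexed network querying: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-indexed network querying: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(refnetq)
```

## The alignment model

A query network `Q = (V_Q, E_Q)` must be a tree; the target
`T = (V_T, E_T)` is an arbitrary undirected network with edge weights
`w(u, v) ∈ [0, 1]`. An alignment maps each query node to a distinct target
node or to nothing (a *deletion*), and may use *inserted* target nodes to
bridge a query edge whose endpoint images are not adjacent in the target.
The target subgraph induced on the matched images plus insertions — the
*alignment subnetwork* — must be connected. The score adds the similarity
of every matched pair, the weight of every query edge whose endpoint images
are adjacent in the target, and the indel penalties
`n_ins·δ_ins + n_del·δ_del`.

Two modeling points deserve emphasis because the score drives everything
else:

* **Bridged edges carry no weight.** A query edge realized as a target path
  of length ≥ 2 contributes only the insertion penalties of the path's
  interior nodes, never the path's edge weights. This keeps the stored
  score of an alignment exactly recomputable from its fields (`matched`,
  `deleted_query`, `inserted_target`) — the package validates that
  invariant on every alignment — whereas a path-weight bonus would depend
  on which bridging path was chosen, information the alignment does not
  retain.
* **Deletions splice.** The query tree is rooted at a node of maximum
  degree (ties broken by smallest identifier); deleting a node re-attaches
  its children to its parent, and the root itself is never deleted. The
  spliced parent–child pairs are not query edges, so they never contribute
  edge weight even when their images happen to be adjacent. The exhaustive
  testing oracle (`brute_force_align`) uses the identical convention, so
  both routes optimize the same objective.

## The color-coding dynamic program

`colorcode_align` runs `t` independent trials. Each trial colors every
target node i.i.d. uniformly with `c` colors and solves, exactly, a tree DP
over states *(query node, hosting target node, used-color subset,
insertions used, deletions used)*. Child transitions allow: a match at an
adjacent target node (collecting the edge weight); a match at distance
`d ≤ 1 + remaining insertion budget` through an enumerated simple bridging
path whose interior nodes consume insertion slots and their colors; or a
child deletion, whose own children then attach to the current host. All
simple bridging paths of length ≤ 3 are enumerated rather than one greedy
shortest path per node pair: the enumeration is deterministic, slightly
more complete, and keeps the engine's result a lower bound on the
exhaustive oracle's optimum by construction.

With `c = |V_Q| + max_ins` colors (or `|free| + max_ins` under forcing —
see induced alignments below), any fixed optimal solution uses at most `c`
nodes, which are simultaneously distinctly colored with probability at
least `p = c!/c^c`. Running

```
t = ceil( log(1 − confidence) / log(1 − p) )
```

trials therefore returns the optimum with probability at least
`confidence` (0.99 by default): `trials_for_confidence(6, 0.99)` is 297.
Using the full-size `p` even when fewer nodes are used makes the stated
confidence a conservative lower bound. Trial `j` seeds its coloring with
`seed + j`, so runs are exactly reproducible; score ties are broken by
fewest indels, then by the lexicographically smallest matched mapping.

Degenerate and edge cases: a single-node query reduces to the best
similarity entry; an infeasible instance (for example a query edge over an
edgeless target with no insertion budget) returns `NULL` rather than an
alignment; queries needing more than 12 colors are refused (the DP state
space is exponential in `c` — at the default caps this admits queries of up
to ten nodes).

## Statistical significance

The null model embeds the query tree at random into the target, preserving
its topology and using no indels: a uniform random root image, then each
query edge follows a uniformly random unused neighbour, resampling on dead
ends (capped at 100× the requested sample count, after which a null-model
error is raised rather than silently under-sampling). Each embedding is
scored with the same formula, and the alignment's z-score is
`(s − μ)/σ` over 10,000 samples by default. A degenerate null (`σ = 0`) is
handled by contract: a score above the null mean counts as significant, at
or below it does not. The significance cut-off for storing index mappings
defaults to 3 — the most permissive value in the studied 3–6 range, which
stores the most mappings; stricter cut-offs store a prefix of the mappings
a laxer cut-off stores (same seeds), which the tests assert.

Whether the random alignments should allow indels is ambiguous; this
implementation keeps them indel-free, matching the "topology-preserving"
reading and keeping the null cheap and seedable.

## Index construction

References are grown by random walks: a uniform seed node, then repeatedly
a uniform target edge incident to the current reference with its outside
endpoint, until `k` nodes (default 6, matching the default query size —
references should resemble the queries they screen). Only the walk's `k−1`
edges are kept, so references are subtrees and legal queries for the
engine. Aligning a reference back to the target uses a target-vs-target
similarity; the synthetic generator always emits one (identity pairs at 1,
optional paralog pairs, sparse background).

`extract_mappings` iterates: align, test significance (always against a
null sampled on the *original* target — the null is a property of the
reference/target pair, and re-sampling it on the shrinking working copy
would make later mappings incomparable with earlier ones), store, remove
the alignment subnetwork, repeat until the first non-significant or
infeasible alignment. Coverage counts every subnetwork node, insertions
included. Initial-set construction stops at η% coverage (default 70%) or
at a hard cap of 500 references — the stopping loop otherwise has no
failure branch — and the final set is the classic greedy set cover
(largest marginal coverage first, ties to the earlier reference), with its
`O(ln |I|)` approximation guarantee, which the tests check against a
brute-forced optimal cover on small instances.

The index serializes to JSON with 17-significant-digit numbers (doubles
round-trip exactly) together with an order-independent checksum of the
target's node and weighted edge sets; loading against a different target
fails with a stale-index error.

## Query processing

For each reference, the query is aligned to it and screened against
`θ · ideal` (default θ = 0.5), where the ideal score is what a perfectly
homologous placement could achieve: every query node at its best
similarity, plus edge weight for at most `min(|E_Q|, k−1)` query edges (a
k-node reference cannot realize more), plus the mandatory deletion
penalties when the query is larger than the reference. A reference with no
positive similarity to the query at all is rejected outright — with no
homological evidence it cannot "represent" the query, and a tiny reference
could otherwise pass on edge weights alone. Accepted references are
processed in descending screening score, so strong candidates set a high
bar early.

Composing the query→reference alignment ψ with a stored reference→target
mapping φ forces `u ↦ φ(ψ(u))` for every query node matched in both steps
(set `S`, image `S′`); nodes dropped by a deletion in either step stay
free. The sign condition on the similarity of forced pairs is vacuous for
similarities in `[0, 1]` and is recorded as always true.

**Upper bound.** The induced alignment's score is bounded by a
maximum-weight bipartite matching over similarities: forced rows contribute
their forced similarity; free rows may match any target node outside `S′`.
Because the matching ignores topology, an aligned-interaction allowance is
added: each query edge with both endpoints forced contributes its realized
target edge weight (zero if the images are not adjacent), every other
query edge the maximum target edge weight; indel penalties are nonpositive
and dropped. A similarity-only matching is *not* a true bound on this
score — positive edge weights can push a real alignment above it — so the
allowance is what makes pruning exact, and the tests assert dominance with
zero tolerance. The matching itself is an exact bitmask dynamic program
over the (at most a handful of) free rows, cross-checked in the tests
against exhaustive assignment enumeration.

Candidates whose bound does not exceed the incumbent (skip on `≤`:
discarding ties cannot lose a strictly better result) are pruned; the rest
run `induced_align`, a forced-pair invocation of the engine with colors
reduced to the free query nodes plus the insertion cap. Forced hosts are
never insertion sites and never host free nodes. Per-candidate seeds
derive from the reference position and mapping index rather than call
order, so pruned and unpruned runs execute identical alignments for the
candidates they share — with the exact bound this makes "pruning never
changes the best score" hold deterministically, which the tests verify.

## The synthetic generator

`generate_target` produces preferential-attachment or Erdős–Rényi graphs
(largest component kept, weights uniform on [0.5, 1]) with density presets
at roughly 4.7, 4.1 and 2.5 interactions per protein — the range spanned by
well-studied bacterial and mouse interactomes. `sample_query` draws
walk-grown subtrees (default 6 nodes). Topology perturbation inserts a
leaf, splits an edge, or deletes a degree-1/2 node (splicing its
neighbours), always returning a tree; a 6-node query yields the 7- and
5-node variants of the standard 3-topology × 4-homology (μ = 0, 5, 10,
20%) design that `run_simulate` writes to disk. Homology perturbation
either mutates amino-acid sequences (each residue independently replaced
with probability μ% by one of the 19 other residues, with sequence-identity
similarity as the BLAST-free surrogate) or, without sequences, decays the
similarity matrix toward a uniform [0, 0.1] background. `plant_motif`
embeds a query as a subtree at a known site with similarity 1 against a
≤ 0.1 background, giving ground truth for recovery tests.

What the generator does *not* emulate: duplication–divergence topology,
correlated experimental noise on edge weights, and BLAST's asymmetric
E-value structure. Passing tests therefore demonstrate the algorithmic
properties (optimality within confidence, bound soundness, index
invariants, recovery of unambiguous signals), not performance on any real
interactome.

## Defaults and the sizes used in the checks

| parameter | default | rationale |
|---|---|---|
| `k`, `m` (reference/query size) | 6 | references should resemble queries; larger queries make the DP impractical at high confidence |
| `eta` (coverage goal) | 70% | middle of the studied 60–80% range |
| `cutoff` (z cut-off) | 3 | most permissive studied value; stores the most mappings |
| `confidence` | 0.99 | standard setting for the engine |
| `max_ins`, `max_del` | 2 | the usual indel cap for this alignment family |
| `delta_ins`, `delta_del` | −0.5 | any fixed nonpositive penalty works; exposed in the config |
| `n_null` | 10,000 | permutation sample for z-scores |
| `theta` (screening fraction) | 0.5 | half the ideal score; exposed as a flag |
| E-value floor | 1e−180 | E-values at or below it map to similarity 1 |

The test and acceptance checks run at deliberately small sizes chosen so
the exhaustive oracle stays exact and the whole suite runs quickly: oracle
comparisons use 3–5-node queries against 8–12-node targets with
`max_ins = max_del = 1`; index fixtures use 25-node targets with 3-node
references at η = 60% and 200-sample nulls; planted-recovery instances use
13-node targets, 3-node queries and edge-sized (k = 2) references pooled
from three initial sets — small references make it likely that some stored
mapping lies wholly inside the planted site, which is what lets the forced
pairs seed a correct induced alignment. These sizes are the package's
evaluation conditions, not limits of the implementation.

## Known limitations

* Queries must be trees (the engine's DP requires it); arbitrary query
  topologies are out of scope.
* The trial-count calibration is conservative; fewer trials often suffice
  in practice, so runtimes overestimate what a tuned confidence schedule
  could achieve.
* The bipartite bound is loose when the query has many edges and the
  target has heavy edge weights (the allowance uses the maximum weight),
  which reduces pruning, never correctness.
* Screening depends on θ and on how well references resemble queries; a
  reference set built at small `k` screens weakly (many acceptances), one
  at large `k` may reject perturbed queries.
* The index is static: a changed target invalidates it (checksum), and
  there is no incremental update.
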