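---
title: "Path covers with subpath and paired constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path covers with subpath and paired constraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcover)
```

## The model

A splicing graph is a DAG whose nodes are pseudo-exons and whose edges record
that two pseudo-exons are consecutive in some transcript. Multi-assembly asks
for a small set of source-to-sink paths explaining the observed reads; the
classical formalization is the minimum path cover (MPC): the fewest directed
paths such that every required node lies on at least one of them. On DAGs the
MPC is polynomial, and its size equals the maximum antichain (Dilworth).

`pathcover` solves the MPC and three constrained extensions:

* **MPC-SC**: required nodes `V'`, required edges `E'`, and subpath
  constraints (long reads, transfrags) that must appear *contiguously* inside
  a solution path.
* **MW-MPC-SC**: the weighted version; paths must start in a set `S`
  (sources plus, e.g., internal transcription start sites) and end in `T`,
  and among minimum-cardinality covers one of minimum total edge weight is
  returned.
* **MPC-PSC**: paired constraints — two subpaths (read mates) that must lie
  on the *same* solution path, though not contiguously with each other.

A single-node sequence is a legal path throughout; without this, an isolated
required node would make instances artificially infeasible.

## The flow engine

The unweighted solver replaces each node `v` by an arc `(v_in, v_out)` with
flow lower bound 1 when `v` is required (0 otherwise); edges, a global source
feeding the DAG's sources and a global sink draining its sinks carry lower
bound 0. A feasible flow of minimum value decomposes into exactly that many
paths, and the minimum value equals the maximum antichain size. The min-flow
is computed by two max-flow applications: a greedy initial feasible flow (one
unit routed source-to-sink through each unsatisfied lower-bound arc) and a
cancellation max-flow from sink to source on the residual network
(shortest-augmenting-path max-flow with integer capacities — simple and
integral, which is all the desk-scale networks here need).

For weighted problems the network gains costs (original edges cost their
weight, structural arcs cost 0) and a return arc from the global sink to the
global source whose cost is the total of all weights plus one. Because no
simple path can cost more than that total, each unit of circulation pays more
for the return arc than for any route, so a minimum-cost circulation first
minimizes the number of paths and then their total weight — the
lexicographic objective. The circulation is solved by the standard
lower-bound transformation (base flow at the bounds, imbalances routed from
a super-source to a super-sink) with successive shortest augmenting paths;
`Inf` capacities are capped at one more than the number of lower-bound arcs,
which no arc can exceed in any minimal solution.

## The reduction for subpath constraints

Subpath constraints are folded into a classical MPC in stages:

1. Node/edge constraints dominated by an edge or subpath constraint are
   dropped (covering the larger object covers them). Single-node subpaths
   become node constraints here, so later stages only see paths with at
   least one edge.
2. Subpaths contained in another are removed; duplicates keep the
   lowest-index copy.
3. While some constraint's suffix equals another's prefix, the pair with the
   *longest* overlap is merged into one constraint (ties: smallest first
   index, then smallest second index). This merge stage is the crux: a
   reduction that skips it mishandles families where one constraint overlaps
   two others by different lengths. `solve_mpc_sc(..., naive = TRUE)`
   exposes that incomplete variant for comparison, and
   `overlap_chain_fixture()` generates the chain families on which it
   returns strictly more paths than the optimum.
4. Each remaining constraint becomes a shortcut edge between its endpoints
   (parallel edges allowed transiently), immediately subdivided by a fresh
   required midpoint node — after which the graph is simple again and all
   constraints are node constraints.
5. Unweighted route: take the transitive closure (recording, for every
   closure edge, a concrete witness path) and keep only required nodes;
   solve classical MPC there. Weighted route: stop before the closure —
   coverage is expressed as flow lower bounds instead, and midpoints carry
   the weight of what they stand for (the summed edge weights of a merged
   subpath, or the weight of an original required edge; assigning the
   latter keeps total weights faithful, since the subdivided edge's two
   halves cost nothing).
6. Solutions are lifted back by expanding closure edges through their
   witnesses and midpoints into their constraints, then re-verified against
   the *original*, untouched constraint sets. A verification failure raises
   rather than returning silently; it would indicate an implementation bug,
   not valid-input behavior.

After merging, the containment filter is re-run as a defensive assertion:
the merge loop cannot terminate while a containment could still form, so any
removal there signals corrupted state and raises.

## Paired constraints

Each constraint (a required node, a required edge, or a pair of subpaths) is
an *atom*; two atoms are compatible iff one directed path contains everything
both contribute. Pairwise compatibility of a set implies a single containing
path on a DAG (the union of the constraints has width 1), so the optimum is
the chromatic number of the incompatibility graph. Deciding joint
containment merges subpaths that share nodes into forced segments — each
node may have at most one forced successor and predecessor — and checks that
the segments are totally ordered by reachability; the witness chains the
segments with shortest-hop connectors (which, on a DAG, can be shown never
to re-enter a segment). `realize_class()` still verifies its witness and
raises if the construction ever failed for a pairwise-compatible class,
rather than trusting the argument blindly.

The chromatic number is computed exactly: an exact maximum-clique lower
bound and a greedy upper bound (via igraph) usually coincide on these highly
structured graphs; when they do not, DSATUR-style backtracking with
new-color symmetry breaking closes the gap. This replaces enumeration of all
set partitions of the atoms — equivalent in outcome, but the coloring search
comfortably handles the 24–25-atom hardness-gadget instances that partition
enumeration cannot. The FPT budget defaults to 20 atoms and is a parameter;
zero atoms yield zero paths, since nothing forces a path to exist.

With only a bipartiteness test one can decide whether two paths suffice
(`solve_opt2()`): an edgeless incompatibility graph means one path (or zero
without atoms), a bipartite one yields a 2-path solution from the color
classes, and an odd cycle certifies that at least three are needed.

## The hardness gadget

`hardness_gadget()` encodes 3-colorability of a non-bipartite graph `G` as a
paired-constraint instance: a backbone with one three-branch block per
vertex and per edge, pairings `(v, [v])` tying each edge-block branch to its
vertex branch, and pairings of every first-stage branch with the tail edge so
that all three branches of a block are forced using paired constraints only.
Three paths exist iff `G` is 3-chromatic; the construction realizes each
color class as one path, and two same-colored endpoints of an edge would
force one path through two parallel branches of the same block. The tests
verify the biconditional on K3, C5, K4 and a pendant-edge variant, with the
source graph's chromatic number computed by exhaustive assignment. The
branches have length 2 (subdivided) so the gadget DAG stays simple; this
stand-in has width 3, and no claim is made about width-2 or series-parallel
refinements of the construction.

## The synthetic generator

`random_splicing_dag()` emulates the splicing-graph setting: ordered
pseudo-exons, each transcript an increasing subsequence (exon inclusion
probability `edge_density`, default 0.5 — alternative isoforms of a gene
typically share about half their exons), consecutive pairs becoming edges,
every exon patched onto some transcript. Defaults are 20 exons and 3
transcripts — a mid-sized alternatively spliced gene — with 10 long reads
spanning 4 consecutive pseudo-exons (thousands of base pairs, several exons,
as third-generation reads do) and 5 read pairs with a 1–3 exon mate gap.
Sampled constraints are windows of a ground-truth transcript, hence always
individually satisfiable, and the transcripts themselves witness that the
constrained optimum never exceeds the transcript count.

The generator does **not** emulate sequencing error (reads are exact
windows), coverage biases, read-to-graph alignment ambiguity, or graph noise
(every edge comes from a true transcript). Passing tests on generated
instances therefore demonstrate correctness of the combinatorial solvers on
clean splicing-like structures, not robustness to noisy alignments —
constraint extraction from real alignments is upstream of this package.

## Numerical and design choices

* **Determinism.** Every tie is broken lexicographically by node identifier
  (radix/C-locale order): topological orders, closure witnesses and
  connectors (breadth-first, shortest hop count first), flow decomposition
  (smallest head-node name, then arc index), merge order (longest overlap,
  then smallest indices). Identical inputs give identical outputs; the
  generators are seeded and reproducible.
* **Integrality.** All flows are integral because capacities and bounds are
  integers and augmentation pushes integer bottlenecks; comparisons use a
  1e-9 slack only to guard floating-point cost accumulation.
* **Degenerate inputs.** Empty graphs, empty constraint sets, edgeless
  graphs, and single-node paths are all legal and tested; an empty required
  set yields an empty cover.
* **Scale.** Reachability is materialized as a dense matrix (refusing
  n > 2000); the intended regime is gene-level graphs of tens to hundreds
  of nodes. The suffix/prefix overlap computation is direct pairwise
  comparison, quadratic in the number of constraints — the right trade-off
  at this scale; the asymptotically optimal all-pairs suffix-prefix
  machinery would produce identical output.
* **Problem sizes in the tests.** The Dilworth identity is checked
  exhaustively on all DAGs with up to 6 nodes (every DAG on `n` labeled
  nodes is a relabeling of one with increasing edges) plus 200 random DAGs
  up to 25 nodes; constrained solvers are compared against exhaustive
  enumeration on 100 instances of up to 8 nodes (50 weighted instances up
  to 7 nodes), where enumeration is still exact and fast.

## Limitations

* MPC-PSC is exponential in the number of constraints by nature; the solver
  refuses instances beyond its budget rather than approximating (no
  polynomial approximation below ratio 4/3 exists unless P = NP).
* Weights must be non-negative; the lexicographic objective (count first,
  weight second) is the only one offered.
* The package starts from a constraint-annotated DAG; building splicing
  graphs from alignments, expression estimation, and coordinate handling are
  out of scope.
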