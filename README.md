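# pathcover

Minimum path covers of directed acyclic graphs with subpath and paired-end
constraints, for transcript multi-assembly and related mixed-sample problems.

## The problem

Genome-guided multi-assembly (RNA-Seq transcripts, viral quasi-species)
commonly reduces to a **Minimum Path Cover (MPC)**: given a splicing or
overlap DAG *G* whose nodes are pseudo-exons, find the fewest directed paths
covering every node — each path a candidate transcript. On a DAG this is
polynomial: by Dilworth's theorem the optimum equals the maximum antichain
size, and it is computed here as a *min-flow with lower bounds* (each node
becomes an arc with flow lower bound 1; any decomposition of a minimum
feasible flow into paths is an MPC).

Long reads and paired-end reads add information that plain MPC ignores.
`pathcover` implements the constrained problem family:

* **MPC-SC** — given required nodes *V′*, required edges *E′* and a family of
  subpath constraints *P<sup>in</sup>* (long reads / transfrags), find the
  fewest paths covering *V′* and *E′* such that every subpath lies
  *contiguously* inside some solution path. Solved in polynomial time by a
  reduction to classical MPC: drop dominated constraints, remove contained
  subpaths, iteratively merge constraints whose suffix equals another's
  prefix (longest overlap first — skipping this merge step is exactly what
  makes earlier reductions incorrect), model each remaining constraint as a
  subdivided shortcut edge with a required midpoint, then take the
  transitive closure induced on the required set.
* **MW-MPC-SC** — the weighted variant with path start/end sets *S* ⊇ sources
  and *T* ⊇ sinks: among minimum-cardinality covers, return one of minimum
  total edge weight. Solved via *min-cost circulation with flow lower bounds*
  (no closure step needed; coverage becomes lower bounds, and a return arc
  priced above any single path's weight makes every min-cost circulation
  simultaneously a min-flow).
* **MPC-PSC** — paired subpath constraints (paired-end reads): the two mates
  must lie on the *same* solution path. NP-hard, but fixed-parameter
  tractable in the number of constraints *C*: the optimum equals the
  chromatic number of the constraint *incompatibility graph* (two constraints
  are incompatible iff no single directed path contains both), computed
  exactly and realized class by class. `solve_opt2()` handles the polynomial
  OPT ≤ 2 case via bipartiteness.

The package also ships independent oracles (bipartite-matching MPC, maximum
antichains, exhaustive constrained cover search), a synthetic splicing-graph
simulator with long-read/paired-end samplers, the NP-hardness gadget that
encodes graph 3-colorability as an MPC-PSC instance, and a CLI.

## Worked example

```r
library(pathcover)

# a weighted diamond: 1 -> {2, 3} -> 4, the 1-2-4 route cheap, 1-3-4 expensive
d <- dag(1:4, list(c("1","2",1), c("1","3",10), c("2","4",1), c("3","4",10)))

# a long read pins 1,2,4 to one transcript; all nodes must be covered
inst <- instance(d, required_nodes = d$nodes, subpaths = list(c("1","2","4")))
solve_mpc_sc(inst)
#> <pc_cover> problem=mpc-sc, k=2, total_weight=2, satisfied=TRUE
#>    3
#>    1 -> 2 -> 4
```

Two paths suffice: one carries the read `(1,2,4)` contiguously, the second
covers the remaining node 3 (a single-node path is a legal cover path). The
weighted solver shows why transcript start sites matter — allowing paths to
start at 3 (e.g. an internal transcription start) avoids the expensive
`1 -> 3` edge:

```r
solve_mw_mpc_sc(instance(d, required_nodes = d$nodes,
                         starts = c("1","3"), ends = "4"))
#> <pc_cover> problem=mw-mpc-sc, k=2, total_weight=12, satisfied=TRUE
#>    1 -> 2 -> 4
#>    3 -> 4
```

(with `starts = "1"` only, the optimum costs 22). Paired constraints are
NP-hard in general; the exact FPT solver still handles them, e.g. the
hardness-reduction instance built from the triangle graph:

```r
src <- named_source_graph("k3")
gd  <- hardness_gadget(src$vertices, src$edges)
solve_mpc_psc(gd$instance, fpt_budget = 40)$k
#> [1] 3        # K3 is 3-chromatic, so exactly 3 paths are needed
```

## Command line

```sh
inst/cli/pathcover simulate --exons 20 --transcripts 3 --long-reads 10 --out gene.json
inst/cli/pathcover mpc-sc gene.json --out cover.json
inst/cli/pathcover verify gene.json cover.json
inst/cli/pathcover gadget --graph k3 --out k3.json
inst/cli/pathcover mpc-psc k3.json --fpt-budget 40
```

Exit codes: 1 malformed/invalid input, 2 infeasible instance, 3 budget
exceeded.

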