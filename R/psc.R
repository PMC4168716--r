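# Paired-subpath-constraint solver. Constraints (nodes, edges, subpaths,
# pairs of subpaths) are atoms; two atoms are compatible iff one directed
# path contains everything both contribute. The minimum number of solution
# paths equals the chromatic number of the atom incompatibility graph
# (pairwise compatibility implies joint realizability on a DAG), which makes
# the problem fixed-parameter tractable in the number of constraints even
# though it is NP-hard in general.

# Atoms carry the list of subpaths they force onto a single solution path:
# node -> one 1-node subpath, edge -> one 2-node subpath, pair -> both
# members, bare subpath constraint -> itself (modelled as a pair with two
# identical members).
constraint_atoms <- function(inst) {
  atoms <- list()
  add <- function(kind, payload, subpaths, label) {
    atoms[[length(atoms) + 1L]] <<- list(kind = kind, payload = payload,
                                         subpaths = subpaths, label = label,
                                         index = length(atoms) + 1L)
  }
  for (v in inst$required_nodes) {
    add("node", v, list(v), sprintf("node %s", v))
  }
  if (nrow(inst$required_edges)) {
    for (i in seq_len(nrow(inst$required_edges))) {
      e <- c(inst$required_edges$from[i], inst$required_edges$to[i])
      add("edge", e, list(e), sprintf("edge %s->%s", e[1], e[2]))
    }
  }
  for (i in seq_along(inst$subpaths)) {
    p <- inst$subpaths[[i]]
    add("pair", list(p, p), list(p),
        sprintf("subpath %d (%s)", i, paste(p, collapse = ",")))
  }
  for (i in seq_along(inst$pairs)) {
    pr <- inst$pairs[[i]]
    add("pair", pr, pr, sprintf("pair %d", i))
  }
  atoms
}

# shared context so the O(C^2) compatibility sweep reuses one reachability
# matrix and index
.pc_psc_ctx <- function(dag) {
  ix <- .pc_index(dag)
  list(ix = ix, reach = .pc_reach_idx(ix),
       topo_pos = {
    pos <- integer(ix$n)
    pos[.pc_topo_idx(ix)] <- seq_len(ix$n)
    pos
  })
}

#' Can a single directed path contain all given subpaths?
#'
#' Decides whether one directed path of the DAG contains every given subpath
#' as a contiguous subsequence, and if so constructs a witness. Subpaths
#' sharing nodes are first merged into forced segments (each node may have at
#' most one forced successor and predecessor); the disjoint segments must then
#' be totally ordered by reachability, and consecutive segments are chained by
#' deterministic shortest-hop connecting paths (in a DAG such connectors
#' cannot re-enter a segment).
#'
#' @param dag a `pc_dag`.
#' @param subpaths list of node sequences (each a valid path of `dag`).
#' @return list with `ok` (logical) and `witness` (a node sequence containing
#'   every subpath, or `NULL`).
#' @export
single_path_contains_all <- function(dag, subpaths) {
  ctx <- .pc_psc_ctx(dag)
  .pc_contains_all(dag, subpaths, ctx)
}

.pc_contains_all <- function(dag, subpaths, ctx) {
  sp <- unique(lapply(subpaths, as.character))
  sp <- sp[lengths(sp) > 0L]
  if (!length(sp)) return(list(ok = TRUE, witness = character()))
  ix <- ctx$ix
  fail <- list(ok = FALSE, witness = NULL)
  mentioned <- unique(unlist(sp))
  mi <- unname(ix$id[mentioned])
  # forced immediate successors/predecessors
  succ <- character(); names(succ) <- character()
  pred <- character(); names(pred) <- character()
  for (p in sp) {
    if (length(p) < 2L) next
    for (k in 2:length(p)) {
      a <- p[k - 1L]; b <- p[k]
      if (!is.na(succ[a]) && succ[a] != b) return(fail)
      if (!is.na(pred[b]) && pred[b] != a) return(fail)
      succ[a] <- b
      pred[b] <- a
    }
  }
  # chains of the forced-edge graph = segments
  starts <- mentioned[is.na(pred[mentioned])]
  seen <- character()
  segments <- list()
  for (s in starts) {
    seg <- s
    v <- s
    while (!is.na(succ[v])) {
      v <- unname(succ[[v]])
      seg <- c(seg, v)
      if (length(seg) > length(mentioned)) return(fail)  # defensive
    }
    segments[[length(segments) + 1L]] <- seg
    seen <- c(seen, seg)
  }
  if (length(seen) != length(mentioned) || anyDuplicated(seen)) {
    return(fail)  # a forced cycle (cannot happen on a DAG) or shared node
  }
  # total order by topological position of segment heads
  heads <- vapply(segments, function(s) s[1], "")
  segments <- segments[order(ctx$topo_pos[unname(ix$id[heads])])]
  if (length(segments) > 1L) {
    for (k in 2:length(segments)) {
      a <- segments[[k - 1L]]
      b <- segments[[k]]
      if (!ctx$reach[ix$id[a[length(a)]], ix$id[b[1]]]) return(fail)
    }
  }
  # chain segments with shortest-hop connectors (lexicographic tie-break)
  witness <- segments[[1]]
  if (length(segments) > 1L) {
    for (k in 2:length(segments)) {
      u <- witness[length(witness)]
      v <- segments[[k]][1]
      conn <- .pc_bfs_path(ix, unname(ix$id[u]), unname(ix$id[v]))
      if (is.null(conn)) return(fail)
      witness <- c(witness, ix$nodes[conn][-1], segments[[k]][-1])
    }
  }
  if (!is_path(dag, witness)) return(fail)
  for (p in sp) if (!.pc_is_contiguous(witness, p)) return(fail)
  list(ok = TRUE, witness = witness)
}

#' Are two constraint atoms compatible?
#'
#' Two constraints are compatible iff some directed path of the DAG contains
#' both entirely (nodes and edges count as 1- and 2-node subpaths; a pair
#' contributes both its members).
#'
#' @param x,y atoms as produced by the solver (or any list with a `subpaths`
#'   element of node sequences).
#' @param dag a `pc_dag`.
#' @return `TRUE` or `FALSE`.
#' @export
atoms_compatible <- function(x, y, dag) {
  single_path_contains_all(dag, c(x$subpaths, y$subpaths))$ok
}

#' Check that every constraint is individually satisfiable
#'
#' A pair whose two members cannot lie on one directed path makes the whole
#' instance infeasible (a single solution path must contain both); required
#' edges must exist and required nodes are trivially satisfiable. Raises
#' `pc_infeasible_error` naming the first offending constraint.
#'
#' @param inst a `pc_instance`.
#' @return invisibly `TRUE` when feasible.
#' @export
check_feasibility <- function(inst) {
  atoms <- constraint_atoms(inst)
  ctx <- .pc_psc_ctx(inst$dag)
  for (a in atoms) {
    if (!.pc_contains_all(inst$dag, a$subpaths, ctx)$ok) {
      pc_infeasible_error(sprintf("constraint %s cannot be satisfied by any single path",
                                  a$label))
    }
  }
  invisible(TRUE)
}

#' Build the constraint incompatibility graph
#'
#' One vertex per constraint atom; an undirected edge joins two atoms iff no
#' directed path of the DAG contains both. The chromatic number of this graph
#' is the optimum of the paired-constraint problem.
#'
#' @param inst a `pc_instance` (feasibility should be checked first).
#' @return object of class `pc_incompat` with `atoms` and the logical
#'   adjacency matrix `adj`.
#' @export
build_incompatibility_graph <- function(inst) {
  atoms <- constraint_atoms(inst)
  C <- length(atoms)
  ctx <- .pc_psc_ctx(inst$dag)
  adj <- matrix(FALSE, C, C)
  if (C >= 2L) {
    for (i in seq_len(C - 1L)) {
      for (j in (i + 1L):C) {
        ok <- .pc_contains_all(inst$dag,
                               c(atoms[[i]]$subpaths, atoms[[j]]$subpaths),
                               ctx)$ok
        adj[i, j] <- adj[j, i] <- !ok
      }
    }
  }
  structure(list(atoms = atoms, adj = adj), class = "pc_incompat")
}

#' @export
print.pc_incompat <- function(x, ...) {
  cat(sprintf("<pc_incompat> %d constraint atoms, %d incompatible pairs\n",
              length(x$atoms), sum(x$adj) / 2))
  invisible(x)
}

#' Export an incompatibility graph to Graphviz DOT
#' @param ig a `pc_incompat`.
#' @param path output file path.
#' @export
write_incompatibility_dot <- function(ig, path) {
  lab <- vapply(ig$atoms, `[[`, "", "label")
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("graph incompatibility {", paste0("  ", q(lab), ";"))
  C <- length(lab)
  if (C >= 2L) {
    for (i in seq_len(C - 1L)) {
      for (j in (i + 1L):C) {
        if (ig$adj[i, j]) lines <- c(lines, sprintf("  %s -- %s;", q(lab[i]), q(lab[j])))
      }
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Realize a pairwise-compatible class of atoms as one path
#'
#' Returns a single directed path containing every atom of the class. The
#' witness is constructed from the union of the atoms' subpaths and verified;
#' a failure raises `pc_realization_error` (for pairwise-compatible input this
#' would be a counterexample to the pairwise-implies-joint property on DAGs
#' and is reported, never silently trusted).
#'
#' @param dag a `pc_dag`.
#' @param atoms list of atoms (see [build_incompatibility_graph()]).
#' @return a node sequence.
#' @export
realize_class <- function(dag, atoms) {
  res <- single_path_contains_all(dag, unlist(lapply(atoms, `[[`, "subpaths"),
                                              recursive = FALSE))
  if (!res$ok) {
    pc_realization_error(sprintf(
      "cannot realize constraint class {%s} as a single path",
      paste(vapply(atoms, `[[`, "", "label"), collapse = "; ")))
  }
  res$witness
}

#' Decide whether two paths suffice (and solve if so)
#'
#' Polynomial special case: the optimum is at most 2 iff the incompatibility
#' graph is bipartite. An edgeless graph means one path suffices (zero paths
#' when there are no constraints at all); a bipartite graph with at least one
#' edge yields a 2-path solution realized from the two color classes; a
#' non-bipartite graph means the optimum is at least 3 and `NULL` is
#' returned.
#'
#' @param inst a `pc_instance`.
#' @return a `pc_cover` with `k <= 2`, or `NULL`.
#' @export
solve_opt2 <- function(inst) {
  check_feasibility(inst)
  ig <- build_incompatibility_graph(inst)
  C <- length(ig$atoms)
  if (C == 0L) {
    return(cover_solution(list(), inst$dag, "mpc-psc", satisfied = TRUE))
  }
  if (!any(ig$adj)) {
    paths <- list(realize_class(inst$dag, ig$atoms))
  } else {
    g <- igraph::graph_from_adjacency_matrix(ig$adj, mode = "undirected")
    bm <- igraph::bipartite_mapping(g)
    if (!bm$res) return(NULL)
    side <- bm$type
    paths <- list(realize_class(inst$dag, ig$atoms[!side]),
                  realize_class(inst$dag, ig$atoms[side]))
  }
  chk <- verify_cover(inst, paths)
  if (!chk$ok) {
    pc_realization_error(paste0("realized classes violate constraints: ",
                                paste(chk$failures, collapse = "; ")))
  }
  cover_solution(paths, inst$dag, "mpc-psc", satisfied = TRUE)
}

#' Exact solver for path cover with paired subpath constraints
#'
#' Fixed-parameter-tractable exact solver: the minimum number of solution
#' paths equals the chromatic number of the constraint incompatibility graph;
#' an optimal coloring is computed exactly and each color class is realized
#' as one witness path. Exponential only in the number of constraints `C`
#' (bounded by `fpt_budget`), polynomial in the graph size.
#'
#' @param inst a `pc_instance` (pairs allowed).
#' @param fpt_budget maximum number of constraint atoms accepted (default
#'   20); beyond it a `pc_limit_error` is raised.
#' @return a `pc_cover` with `problem = "mpc-psc"`.
#' @export
solve_mpc_psc <- function(inst, fpt_budget = 20L) {
  if (fpt_budget < 1L) pc_validation_error("fpt_budget must be >= 1")
  check_feasibility(inst)
  ig <- build_incompatibility_graph(inst)
  C <- length(ig$atoms)
  if (C == 0L) {
    return(cover_solution(list(), inst$dag, "mpc-psc", satisfied = TRUE))
  }
  if (C > fpt_budget) {
    pc_limit_error(sprintf("instance has %d constraints, over the FPT budget of %d",
                           C, fpt_budget))
  }
  col <- chromatic_number(ig$adj)
  paths <- lapply(seq_len(col$k), function(cls) {
    realize_class(inst$dag, ig$atoms[col$coloring == cls])
  })
  chk <- verify_cover(inst, paths)
  if (!chk$ok) {
    pc_realization_error(paste0("realized classes violate constraints: ",
                                paste(chk$failures, collapse = "; ")))
  }
  cover_solution(paths, inst$dag, "mpc-psc", satisfied = TRUE)
}
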