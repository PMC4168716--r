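# Public solvers for the path-cover family. All of them verify the returned
# cover against the untouched input constraints before handing it back.

#' Minimum path cover of a DAG
#'
#' Computes a minimum-cardinality set of directed paths covering the
#' `required` nodes (all nodes by default) via the min-flow reduction: every
#' node becomes an arc with flow lower bound 1 (0 when not required), and the
#' value of a minimum feasible flow equals the size of a maximum antichain,
#' hence the size of a minimum path cover. With `weighted = TRUE` the solver
#' switches to the min-cost-circulation formulation and returns, among all
#' minimum-cardinality covers whose paths run from the sources to the sinks,
#' one of minimum total edge weight (shared edges counted once per use).
#'
#' @param dag a `pc_dag`.
#' @param required nodes to cover (default all; non-required nodes may still
#'   be used as through-nodes).
#' @param weighted minimize total edge weight among minimum covers.
#' @return a `pc_cover` with `problem = "mpc"`.
#' @examples
#' d <- dag(1:4, list(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
#' solve_mpc(d)$k   # the diamond needs 2 paths
#' @export
solve_mpc <- function(dag, required = NULL, weighted = FALSE) {
  if (is.null(required)) required <- dag$nodes
  required <- as.character(required)
  if (!all(required %in% dag$nodes)) {
    pc_validation_error("required contains nodes absent from the graph")
  }
  if (weighted) {
    net <- build_mincost_network(dag, required = required)
    fl <- min_cost_circulation(net)
  } else {
    net <- build_minflow_network(dag, required = required)
    fl <- min_flow(net)
  }
  dec <- decompose_flow_to_paths(fl)
  # paths come off the flow decomposition edge by edge; the independent check
  # here is coverage of the required set
  covered <- unique(unlist(dec$paths))
  if (!all(required %in% covered)) {
    pc_decomposition_error("flow decomposition does not cover the required set")
  }
  cover_solution(dec$paths, dag, "mpc", satisfied = TRUE)
}

#' Minimum path cover with subpath constraints
#'
#' Solves the unweighted constrained problem: find the minimum number of
#' directed paths such that every required node and edge is covered and every
#' subpath constraint (a long read or transfrag) is contained contiguously in
#' some solution path. The instance is reduced to a classical MPC by the
#' merge/shortcut/closure pipeline, solved with the min-flow engine, and the
#' cover is lifted back and re-verified against the original constraints.
#'
#' @param inst a `pc_instance` without pair constraints and without posed
#'   `S`/`T` sets.
#' @param naive run the incomplete reduction that skips containment removal
#'   and suffix/prefix merging (testing only; may return a suboptimal or
#'   violating cover, reported via `satisfied = FALSE`).
#' @return a `pc_cover` with `problem = "mpc-sc"`.
#' @export
solve_mpc_sc <- function(inst, naive = FALSE) {
  if (length(inst$pairs)) {
    pc_validation_error("instance has paired constraints; use solve_mpc_psc()")
  }
  if (!is.null(inst$starts) || !is.null(inst$ends)) {
    pc_validation_error("instance poses S/T sets; use solve_mw_mpc_sc()")
  }
  red <- reduce_to_classic_mpc(inst, naive = naive)
  base <- solve_mpc(red$reduced)
  lift_solution(base$paths, red$trace, problem = "mpc-sc", strict = !naive)
}

#' Minimum-weight minimum path cover with subpath constraints
#'
#' The weighted variant: among all minimum-cardinality covers satisfying the
#' node/edge/subpath constraints whose paths start in `S` and end in `T`,
#' returns one of minimum total edge weight. Runs the normalization, merging
#' and subdivision steps only (no transitive closure — the coverage
#' constraints become flow lower bounds instead), builds the min-cost
#' circulation network and decomposes the optimum into paths.
#'
#' @param inst a `pc_instance` without pair constraints. If `starts`/`ends`
#'   are not posed they default to exactly the sources/sinks of the DAG.
#' @return a `pc_cover` with `problem = "mw-mpc-sc"`.
#' @export
solve_mw_mpc_sc <- function(inst) {
  if (length(inst$pairs)) {
    pc_validation_error("instance has paired constraints; use solve_mpc_psc()")
  }
  starts <- if (is.null(inst$starts)) sources_of(inst$dag) else inst$starts
  ends <- if (is.null(inst$ends)) sinks_of(inst$dag) else inst$ends
  inst_posed <- instance(inst$dag, inst$required_nodes, inst$required_edges,
                         inst$subpaths, starts = starts, ends = ends)
  tr <- .pc_transform16(inst_posed)
  node_cost <- stats::setNames(vapply(tr$midpoints, `[[`, 0, "weight"),
                               vapply(tr$midpoints, `[[`, "", "node"))
  net <- build_mincost_network(tr$tdag, required = tr$vprime,
                               starts = starts, ends = ends,
                               node_cost = node_cost)
  fl <- min_cost_circulation(net)
  dec <- decompose_flow_to_paths(fl)
  tr$witness <- NULL
  class(tr) <- "pc_trace"
  tr$original <- inst_posed
  lift_solution(dec$paths, tr, problem = "mw-mpc-sc", strict = TRUE)
}
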