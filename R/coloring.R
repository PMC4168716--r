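# Exact graph coloring for the FPT solver. The chromatic number is bracketed
# by an exact maximum-clique lower bound and a greedy upper bound (both via
# igraph), then closed by DSATUR-style backtracking with new-color symmetry
# breaking. Intended for constraint incompatibility graphs of a few dozen
# vertices.

#' Exact chromatic number with an optimal coloring
#'
#' @param adj symmetric logical adjacency matrix (no self-loops).
#' @return list with `k` (chromatic number) and `coloring` (integer vector of
#'   colors `1..k`).
#' @export
chromatic_number <- function(adj) {
  n <- nrow(adj)
  if (is.null(n) || n == 0L) return(list(k = 0L, coloring = integer()))
  if (!any(adj)) return(list(k = 1L, coloring = rep(1L, n)))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  lower <- igraph::clique_num(g)
  greedy <- as.integer(igraph::greedy_vertex_coloring(g))
  upper <- max(greedy)
  if (lower == upper) return(list(k = upper, coloring = greedy))
  for (k in lower:(upper - 1L)) {
    col <- .pc_kcolor(adj, k)
    if (!is.null(col)) return(list(k = k, coloring = col))
  }
  list(k = upper, coloring = greedy)
}

# DSATUR branch-and-bound: is the graph k-colorable? Returns a coloring or
# NULL. Deterministic vertex and color choice.
.pc_kcolor <- function(adj, k) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  color <- integer(n)
  # neighbor color sets tracked as a logical matrix n x k
  neigh_used <- matrix(FALSE, n, k)
  rec <- function(ncolored, maxused) {
    if (ncolored == n) return(TRUE)
    un <- which(color == 0L)
    sat <- rowSums(neigh_used[un, , drop = FALSE])
    pick <- un[order(-sat, -deg[un], un)[1]]
    limit <- min(k, maxused + 1L)
    for (cc in seq_len(limit)) {
      if (neigh_used[pick, cc]) next
      color[pick] <<- cc
      nb <- which(adj[pick, ] & color == 0L)
      changed <- nb[!neigh_used[cbind(nb, rep(cc, length(nb)))]]
      neigh_used[cbind(changed, rep(cc, length(changed)))] <<- TRUE
      if (rec(ncolored + 1L, max(maxused, cc))) return(TRUE)
      color[pick] <<- 0L
      neigh_used[cbind(changed, rep(cc, length(changed)))] <<- FALSE
    }
    FALSE
  }
  if (rec(0L, 0L)) color else NULL
}
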