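#' Construct a directed acyclic graph
#'
#' The basic container for every solver in the package. Nodes are opaque
#' string identifiers (integers are accepted and stored as strings); edges are
#' ordered pairs of node IDs with an optional non-negative weight
#' (default 0). Construction validates that every edge endpoint is a declared
#' node, that there are no self-loops or duplicated edges, and that the graph
#' is acyclic.
#'
#' @param nodes character (or coercible) vector of node identifiers.
#' @param edges a two- or three-column matrix/data.frame (`from`, `to`,
#'   optional `weight`), or a list of length-2/3 vectors, or `NULL` for an
#'   edgeless graph.
#' @param weights optional numeric vector of edge weights overriding a third
#'   column; recycled checkably (length 1 or `m`).
#' @return an object of class `pc_dag` with elements `nodes` (character) and
#'   `edges` (data.frame `from`, `to`, `weight`).
#' @examples
#' d <- dag(1:4, list(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
#' d
#' @export
dag <- function(nodes, edges = NULL, weights = NULL) {
  nodes <- as.character(nodes)
  if (anyNA(nodes) || any(nodes == "")) {
    pc_validation_error("node identifiers must be non-missing, non-empty strings")
  }
  if (anyDuplicated(nodes)) {
    pc_validation_error("duplicated node identifiers")
  }
  ed <- .pc_as_edge_df(edges)
  if (is.null(weights)) {
    weights <- ed$weight
  } else {
    weights <- as.numeric(weights)
    if (length(weights) == 1L) weights <- rep(weights, nrow(ed))
    if (length(weights) != nrow(ed)) {
      pc_validation_error("weights must have one value per edge")
    }
  }
  if (any(is.na(weights)) || any(weights < 0)) {
    pc_validation_error("edge weights must be non-negative")
  }
  ed$weight <- weights
  miss <- setdiff(unique(c(ed$from, ed$to)), nodes)
  if (length(miss)) {
    pc_validation_error(sprintf("edge endpoint(s) not declared as nodes: %s",
                                paste(miss, collapse = ", ")))
  }
  if (any(ed$from == ed$to)) {
    pc_validation_error("self-loops are not allowed")
  }
  if (anyDuplicated(paste(ed$from, ed$to, sep = "\r"))) {
    pc_validation_error("duplicated edges")
  }
  g <- structure(list(nodes = nodes, edges = ed), class = "pc_dag")
  # acyclicity check: raises pc_cycle_error on failure
  topological_order(g)
  g
}

.pc_as_edge_df <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (!is.data.frame(edges) && length(edges) == 0L)) {
    return(data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    lens <- lengths(edges)
    if (!all(lens %in% c(2L, 3L))) {
      pc_format_error("each edge must be [from, to] or [from, to, weight]")
    }
    from <- vapply(edges, function(e) as.character(e[[1]]), "")
    to <- vapply(edges, function(e) as.character(e[[2]]), "")
    w <- vapply(edges, function(e) if (length(e) >= 3L) as.numeric(e[[3]]) else 0, 0)
    return(data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) pc_format_error("edges need at least from/to columns")
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3]]) else rep(0, nrow(edges))
  data.frame(from = as.character(edges[[1]]), to = as.character(edges[[2]]),
             weight = w, stringsAsFactors = FALSE)
}

#' @export
print.pc_dag <- function(x, ...) {
  cat(sprintf("<pc_dag> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    shown <- utils::head(x$edges, 8L)
    cat(paste0("  ", shown$from, " -> ", shown$to,
               ifelse(shown$weight != 0, sprintf(" (w=%g)", shown$weight), ""),
               collapse = "\n"), "\n")
    if (nrow(x$edges) > 8L) cat(sprintf("  ... %d more\n", nrow(x$edges) - 8L))
  }
  invisible(x)
}

n_nodes <- function(dag) length(dag$nodes)
n_edges <- function(dag) nrow(dag$edges)

# Index cache: integer ids, adjacency lists (successors sorted by lexicographic
# node rank -> deterministic traversal everywhere), topological order.
.pc_index <- function(dag) {
  nodes <- dag$nodes
  n <- length(nodes)
  id <- seq_len(n)
  names(id) <- nodes
  # lexicographic rank in C locale, stable and locale-independent
  rank <- integer(n)
  rank[order(nodes, method = "radix")] <- seq_len(n)
  from_i <- unname(id[dag$edges$from])
  to_i <- unname(id[dag$edges$to])
  adj_out <- vector("list", n)
  adj_in <- vector("list", n)
  if (length(from_i)) {
    o <- order(rank[to_i], method = "radix")
    sp <- split(to_i[o], factor(from_i[o], levels = id))
    adj_out <- unname(sp)
    o2 <- order(rank[from_i], method = "radix")
    sp2 <- split(from_i[o2], factor(to_i[o2], levels = id))
    adj_in <- unname(sp2)
  } else {
    for (i in id) { adj_out[[i]] <- integer(); adj_in[[i]] <- integer() }
  }
  list(n = n, nodes = nodes, id = id, rank = rank,
       from_i = from_i, to_i = to_i, adj_out = adj_out, adj_in = adj_in)
}

# Kahn's algorithm over indices with lexicographic tie-break; NULL on cycle.
.pc_topo_idx <- function(ix) {
  n <- ix$n
  indeg <- tabulate(ix$to_i, nbins = n)
  # available nodes kept as a logical mask; pick min lexicographic rank
  avail <- indeg == 0L
  out <- integer(n)
  ranks <- ix$rank
  for (k in seq_len(n)) {
    cand <- which(avail)
    if (!length(cand)) return(NULL)
    v <- cand[which.min(ranks[cand])]
    out[k] <- v
    avail[v] <- FALSE
    for (w in ix$adj_out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail[w] <- TRUE
    }
  }
  out
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with a deterministic tie-break: among the available nodes
#' the one with the lexicographically smallest identifier is emitted first.
#'
#' @param dag a `pc_dag` (or a structurally identical list that has not been
#'   validated yet; a cycle raises a `pc_cycle_error`).
#' @return character vector of node IDs; every edge goes forward in it.
#' @export
topological_order <- function(dag) {
  ix <- .pc_index(dag)
  ord <- .pc_topo_idx(ix)
  if (is.null(ord)) pc_cycle_error("graph contains a directed cycle")
  dag$nodes[ord]
}

#' Reachability relation of a DAG
#'
#' Dense boolean relation: `R[u, v]` is `TRUE` iff there is a directed path
#' from `u` to `v` of length >= 0; the relation is reflexive by convention.
#' Materialized as an n x n matrix (intended for desk-scale graphs; refuses
#' n > 2000).
#'
#' @param dag a `pc_dag`.
#' @return logical matrix with node IDs as dimnames.
#' @export
reachability <- function(dag) {
  ix <- .pc_index(dag)
  if (ix$n > 2000L) pc_limit_error("dense reachability is limited to n <= 2000")
  .pc_reach_idx(ix)
}

.pc_reach_idx <- function(ix) {
  n <- ix$n
  ord <- .pc_topo_idx(ix)
  if (is.null(ord)) pc_cycle_error("graph contains a directed cycle")
  R <- diag(n) > 0
  if (n == 0L) {
    dimnames(R) <- list(ix$nodes, ix$nodes)
    return(R)
  }
  for (v in rev(ord)) {
    succ <- ix$adj_out[[v]]
    for (w in succ) R[v, ] <- R[v, ] | R[w, ]
  }
  dimnames(R) <- list(ix$nodes, ix$nodes)
  R
}

# Deterministic shortest-hop path u -> v (indices) via BFS whose frontier is
# expanded in lexicographic-rank order. Returns integer node index sequence or
# NULL if unreachable. `forbid`: optional logical mask of interior nodes to
# avoid.
.pc_bfs_path <- function(ix, u, v, forbid = NULL) {
  if (u == v) return(u)
  n <- ix$n
  parent <- integer(n)
  seen <- logical(n)
  seen[u] <- TRUE
  frontier <- u
  while (length(frontier)) {
    nxt <- integer()
    for (a in frontier) {
      for (b in ix$adj_out[[a]]) {   # already sorted lexicographically
        if (seen[b]) next
        if (!is.null(forbid) && forbid[b] && b != v) next
        seen[b] <- TRUE
        parent[b] <- a
        if (b == v) {
          path <- b
          while (path[1] != u) path <- c(parent[path[1]], path)
          return(path)
        }
        nxt <- c(nxt, b)
      }
    }
    frontier <- nxt
  }
  NULL
}

#' Transitive closure with path witnesses
#'
#' Returns the transitive closure of `dag` (an edge `(u, v)` for every ordered
#' pair of distinct nodes with a directed `u -> v` path) together with a
#' witness map giving, for every closure edge, one concrete path of the input
#' graph. Witnesses are chosen deterministically (shortest hop count,
#' lexicographic tie-break); every input edge is its own witness.
#'
#' @param dag a `pc_dag`.
#' @return list with `closure` (a `pc_dag`, weights dropped to 0) and
#'   `witness` (nested list: `witness[[u]][[v]]` is a character node sequence).
#' @export
transitive_closure <- function(dag) {
  ix <- .pc_index(dag)
  R <- .pc_reach_idx(ix)
  n <- ix$n
  witness <- stats::setNames(vector("list", n), ix$nodes)
  from <- character()
  to <- character()
  for (u in seq_len(n)) {
    vs <- which(R[u, ])
    vs <- vs[vs != u]
    wl <- list()
    for (v in vs) {
      p <- .pc_bfs_path(ix, u, v)
      wl[[ix$nodes[v]]] <- ix$nodes[p]
    }
    witness[[u]] <- wl
    if (length(vs)) {
      from <- c(from, rep(ix$nodes[u], length(vs)))
      to <- c(to, ix$nodes[vs])
    }
  }
  closure <- dag(dag$nodes, data.frame(from = from, to = to,
                                       stringsAsFactors = FALSE))
  list(closure = closure, witness = witness)
}

# ---- path helpers -----------------------------------------------------------

#' Is a node sequence a path of the DAG?
#'
#' A path is an ordered sequence of at least one declared node in which every
#' consecutive pair is an edge (single-node paths are legal).
#'
#' @param dag a `pc_dag`.
#' @param nodes character vector of node IDs.
#' @return `TRUE` or `FALSE`.
#' @export
is_path <- function(dag, nodes) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) return(FALSE)
  if (!all(nodes %in% dag$nodes)) return(FALSE)
  if (anyDuplicated(nodes)) return(FALSE)
  if (length(nodes) == 1L) return(TRUE)
  key <- paste(dag$edges$from, dag$edges$to, sep = "\r")
  all(paste(nodes[-length(nodes)], nodes[-1], sep = "\r") %in% key)
}

path_weight <- function(dag, nodes) {
  if (length(nodes) < 2L) return(0)
  key <- paste(dag$edges$from, dag$edges$to, sep = "\r")
  idx <- match(paste(nodes[-length(nodes)], nodes[-1], sep = "\r"), key)
  sum(dag$edges$weight[idx])
}

# contiguous subsequence test (used for subpath-constraint satisfaction)
.pc_is_contiguous <- function(haystack, needle) {
  haystack <- unname(haystack); needle <- unname(needle)
  nh <- length(haystack); nn <- length(needle)
  if (nn > nh) return(FALSE)
  if (nn == 0L) return(TRUE)
  hit <- which(haystack == needle[1])
  for (s in hit) {
    if (s + nn - 1L <= nh && identical(haystack[s:(s + nn - 1L)], needle)) {
      return(TRUE)
    }
  }
  FALSE
}

sources_of <- function(dag) setdiff(dag$nodes, dag$edges$to)
sinks_of <- function(dag) setdiff(dag$nodes, dag$edges$from)
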