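# light-weight data.frame assembly (skips the expensive checks of
# data.frame(); columns must already be equal-length atomic vectors)
.pc_fast_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = if (length(cols[[1]])) seq_along(cols[[1]]) else integer())
}

# Flow engines: min-flow with lower bounds (two max-flow applications) and
# min-cost circulation with lower bounds (lower-bound transformation +
# successive shortest augmenting paths). These power every solver; networks
# are plain index-based lists so the exhaustive test sweeps stay fast.

#' Construct a flow network
#'
#' Arcs carry an integer lower bound, a capacity (may be `Inf`) and a
#' non-negative cost per unit of flow. A distinguished global source `s` and
#' sink `t` exist; an optional circulation arc `(t, s)` turns s-t flows into
#' circulations.
#'
#' @param node_names character vector naming the network nodes (first two are
#'   conventionally the global source and sink).
#' @param arcs data.frame with columns `tail`, `head` (indices into
#'   `node_names`), `lower`, `cap`, `cost`, plus bookkeeping columns `kind`
#'   (`"node"`, `"edge"`, `"source"`, `"sink"`, `"circ"`) and `ref` (original
#'   node/edge identifier or `NA`).
#' @param s,t integer indices of the global source/sink.
#' @param circ integer index of the circulation arc in `arcs`, or `NA`.
#' @return object of class `pc_flownet`.
#' @export
flow_network <- function(node_names, arcs, s, t, circ = NA_integer_) {
  stopifnot(is.data.frame(arcs),
            all(c("tail", "head", "lower", "cap", "cost") %in% names(arcs)))
  if (any(arcs$lower > arcs$cap)) {
    pc_validation_error("arc lower bound exceeds capacity")
  }
  if (any(arcs$cost < 0)) pc_validation_error("arc costs must be non-negative")
  if (!"kind" %in% names(arcs)) arcs$kind <- NA_character_
  if (!"ref" %in% names(arcs)) arcs$ref <- NA_character_
  structure(list(node_names = node_names, arcs = arcs,
                 s = as.integer(s), t = as.integer(t),
                 circ = as.integer(circ)),
            class = "pc_flownet")
}

#' @export
print.pc_flownet <- function(x, ...) {
  cat(sprintf("<pc_flownet> %d nodes, %d arcs (%d with lower bound >= 1)%s\n",
              length(x$node_names), nrow(x$arcs), sum(x$arcs$lower >= 1),
              if (!is.na(x$circ)) ", circulation arc present" else ""))
  invisible(x)
}

# Edmonds-Karp max-flow on arc arrays (parallel arcs allowed). Returns the
# per-arc flow and its value. Capacities must be finite.
.pc_maxflow <- function(nnode, tail, head, cap, s, t) {
  A <- length(tail)
  flow <- numeric(A)
  if (A == 0L || s == t) return(list(flow = flow, value = 0))
  # residual arc ids: 1..A forward, A+1..2A backward
  rt <- c(tail, head)
  rh <- c(head, tail)
  adj <- vector("list", nnode)
  grp <- split(seq_len(2L * A), rt)
  adj[as.integer(names(grp))] <- grp
  value <- 0
  repeat {
    # BFS for an augmenting path in the residual graph
    parent_arc <- integer(nnode)
    seen <- logical(nnode)
    seen[s] <- TRUE
    frontier <- s
    found <- FALSE
    while (length(frontier) && !found) {
      nxt <- integer()
      for (v in frontier) {
        for (aid in adj[[v]]) {
          res <- if (aid <= A) cap[aid] - flow[aid] else flow[aid - A]
          if (res <= 0) next
          w <- rh[aid]
          if (seen[w]) next
          seen[w] <- TRUE
          parent_arc[w] <- aid
          if (w == t) { found <- TRUE; break }
          nxt <- c(nxt, w)
        }
        if (found) break
      }
      frontier <- nxt
    }
    if (!found) break
    # bottleneck along the path
    v <- t
    bott <- Inf
    while (v != s) {
      aid <- parent_arc[v]
      res <- if (aid <= A) cap[aid] - flow[aid] else flow[aid - A]
      bott <- min(bott, res)
      v <- rt[aid]
    }
    v <- t
    while (v != s) {
      aid <- parent_arc[v]
      if (aid <= A) flow[aid] <- flow[aid] + bott
      else flow[aid - A] <- flow[aid - A] - bott
      v <- rt[aid]
    }
    value <- value + bott
  }
  list(flow = flow, value = value)
}

# finite stand-in for unbounded capacities: no arc ever needs to carry more
# than the number of lower-bound arcs
.pc_cap_finite <- function(arcs) {
  M <- sum(arcs$lower) + 1
  cap <- arcs$cap
  cap[!is.finite(cap)] <- M
  cap
}

#' Minimum-value feasible flow
#'
#' Solves the min-flow problem on a network with arc lower bounds by two
#' max-flow applications: a greedy initial feasible flow (one unit routed
#' s -> arc -> t per unsatisfied lower bound), then cancellation of surplus
#' flow via a max-flow computation from `t` to `s` on the residual network.
#'
#' @param net a `pc_flownet` without circulation arc (it is ignored if present
#'   but unused by this routine's construction helpers).
#' @return list of class `pc_flow` with `flow` (per-arc values), `value`.
#' @export
min_flow <- function(net) {
  arcs <- net$arcs
  A <- nrow(arcs)
  nnode <- length(net$node_names)
  cap <- .pc_cap_finite(arcs)
  flow <- numeric(A)
  if (A) {
    # static adjacency over arcs for the greedy routing phase
    adj <- vector("list", nnode)
    grp <- split(seq_len(A), arcs$tail)
    adj[as.integer(names(grp))] <- grp
    route <- function(from, to) {
      # BFS over arcs, returns arc id sequence or NULL
      if (from == to) return(integer())
      parent <- integer(nnode)
      seen <- logical(nnode)
      seen[from] <- TRUE
      frontier <- from
      while (length(frontier)) {
        nxt <- integer()
        for (v in frontier) {
          for (aid in adj[[v]]) {
            w <- arcs$head[aid]
            if (seen[w]) next
            seen[w] <- TRUE
            parent[w] <- aid
            if (w == to) {
              seq <- integer()
              u <- to
              while (u != from) { seq <- c(parent[u], seq); u <- arcs$tail[parent[u]] }
              return(seq)
            }
            nxt <- c(nxt, w)
          }
        }
        frontier <- nxt
      }
      NULL
    }
    need <- which(arcs$lower > 0)
    for (aid in need) {
      while (flow[aid] < arcs$lower[aid]) {
        up <- route(net$s, arcs$tail[aid])
        down <- route(arcs$head[aid], net$t)
        if (is.null(up) || is.null(down)) {
          pc_infeasible_error(sprintf(
            "lower bound on arc %d (%s -> %s) cannot be met: no s-t route through it",
            aid, net$node_names[arcs$tail[aid]], net$node_names[arcs$head[aid]]))
        }
        for (x in c(up, aid, down)) flow[x] <- flow[x] + 1
      }
    }
    # cancellation: max-flow t -> s on the residual network
    rt <- c(arcs$tail, arcs$head)
    rh <- c(arcs$head, arcs$tail)
    rc <- c(cap - flow, flow - arcs$lower)
    mf <- .pc_maxflow(nnode, rt, rh, rc, net$t, net$s)
    g <- mf$flow
    flow <- flow + g[seq_len(A)] - g[A + seq_len(A)]
  }
  value <- sum(flow[arcs$tail == net$s]) - sum(flow[arcs$head == net$s])
  structure(list(flow = flow, value = value, net = net), class = "pc_flow")
}

#' Minimum-cost circulation with lower bounds
#'
#' Standard lower-bound transformation: the bound of every arc is pushed as a
#' base flow, imbalances are routed from a super-source to a super-sink, and
#' the remaining min-cost max-flow is computed by successive shortest
#' augmenting paths (Bellman-Ford distances, so negative residual costs are
#' handled). Raises `pc_infeasible_error` if the lower bounds admit no
#' circulation.
#'
#' @param net a `pc_flownet` containing a circulation arc.
#' @return list of class `pc_flow` with `flow`, `value` (flow on the
#'   circulation arc) and `cost` (total cost).
#' @export
min_cost_circulation <- function(net) {
  if (is.na(net$circ)) pc_validation_error("network has no circulation arc")
  arcs <- net$arcs
  A <- nrow(arcs)
  nnode <- length(net$node_names)
  cap <- .pc_cap_finite(arcs)
  base <- arcs$lower
  excess <- numeric(nnode)
  for (i in seq_len(A)) {
    if (base[i] > 0) {
      excess[arcs$head[i]] <- excess[arcs$head[i]] + base[i]
      excess[arcs$tail[i]] <- excess[arcs$tail[i]] - base[i]
    }
  }
  SS <- nnode + 1L
  TT <- nnode + 2L
  xt <- arcs$tail; xh <- arcs$head
  xc <- cap - base; xw <- arcs$cost
  pos <- which(excess > 0); neg <- which(excess < 0)
  xt <- c(xt, rep(SS, length(pos)), neg)
  xh <- c(xh, pos, rep(TT, length(neg)))
  xc <- c(xc, excess[pos], -excess[neg])
  xw <- c(xw, numeric(length(pos) + length(neg)))
  total_need <- sum(excess[pos])
  res <- .pc_mcmf(nnode + 2L, xt, xh, xc, xw, SS, TT)
  if (res$value < total_need - 1e-9) {
    pc_infeasible_error("arc lower bounds admit no feasible circulation")
  }
  flow <- base + res$flow[seq_len(A)]
  structure(list(flow = flow, value = flow[net$circ],
                 cost = sum(flow * arcs$cost), net = net),
            class = "pc_flow")
}

# min-cost max-flow by successive shortest paths (Bellman-Ford / SPFA);
# adequate at desk scale, exact for integral capacities.
.pc_mcmf <- function(nnode, tail, head, cap, cost, s, t) {
  A <- length(tail)
  flow <- numeric(A)
  if (A == 0L) return(list(flow = flow, value = 0, cost = 0))
  rt <- c(tail, head)
  rh <- c(head, tail)
  rw <- c(cost, -cost)
  adj <- vector("list", nnode)
  grp <- split(seq_len(2L * A), rt)
  adj[as.integer(names(grp))] <- grp
  value <- 0; total_cost <- 0
  repeat {
    dist <- rep(Inf, nnode)
    dist[s] <- 0
    parent_arc <- integer(nnode)
    inq <- logical(nnode)
    queue <- s
    inq[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; inq[v] <- FALSE
      dv <- dist[v]
      for (aid in adj[[v]]) {
        res <- if (aid <= A) cap[aid] - flow[aid] else flow[aid - A]
        if (res <= 1e-12) next
        w <- rh[aid]
        nd <- dv + rw[aid]
        if (nd < dist[w] - 1e-12) {
          dist[w] <- nd
          parent_arc[w] <- aid
          if (!inq[w]) { queue <- c(queue, w); inq[w] <- TRUE }
        }
      }
    }
    if (!is.finite(dist[t])) break
    v <- t; bott <- Inf
    while (v != s) {
      aid <- parent_arc[v]
      res <- if (aid <= A) cap[aid] - flow[aid] else flow[aid - A]
      bott <- min(bott, res)
      v <- rt[aid]
    }
    v <- t
    while (v != s) {
      aid <- parent_arc[v]
      if (aid <= A) flow[aid] <- flow[aid] + bott
      else flow[aid - A] <- flow[aid - A] - bott
      v <- rt[aid]
    }
    value <- value + bott
    total_cost <- total_cost + bott * dist[t]
  }
  list(flow = flow, value = value, cost = total_cost)
}

# ---- network builders -------------------------------------------------------

#' Build the min-flow network for (classical) MPC
#'
#' Every node `v` of the DAG is split into an arc `(v_in, v_out)` with lower
#' bound 1 if `v` is required and 0 otherwise; original edges become
#' zero-bound arcs between the split halves; a global source feeds every
#' source of the DAG and every sink drains into the global sink. The value of
#' a min-flow on this network equals the maximum antichain size of the DAG
#' (when all nodes are required).
#'
#' @param dag a `pc_dag`.
#' @param required character vector of required nodes (default: all).
#' @return a `pc_flownet`; split arcs carry `kind = "node"` and `ref` = node id.
#' @export
build_minflow_network <- function(dag, required = dag$nodes) {
  ix <- .pc_index(dag)
  n <- ix$n
  required <- as.character(required)
  # network node indices: 1 = s, 2 = t, then in(v) = 2 + v, out(v) = 2 + n + v
  node_names <- c("s", "t", paste0("in:", ix$nodes), paste0("out:", ix$nodes))
  inn <- function(v) 2L + v
  outn <- function(v) 2L + n + v
  req <- ix$nodes %in% required
  tail <- inn(seq_len(n)); head <- outn(seq_len(n))
  lower <- as.integer(req); kind <- rep("node", n); ref <- ix$nodes
  if (length(ix$from_i)) {
    tail <- c(tail, outn(ix$from_i)); head <- c(head, inn(ix$to_i))
    lower <- c(lower, integer(length(ix$from_i)))
    kind <- c(kind, rep("edge", length(ix$from_i)))
    ref <- c(ref, paste(dag$edges$from, dag$edges$to, sep = "\r"))
  }
  srcs <- which(tabulate(ix$to_i, nbins = n) == 0L)
  snks <- which(tabulate(ix$from_i, nbins = n) == 0L)
  if (n) {
    tail <- c(tail, rep(1L, length(srcs)), outn(snks))
    head <- c(head, inn(srcs), rep(2L, length(snks)))
    lower <- c(lower, integer(length(srcs) + length(snks)))
    kind <- c(kind, rep("source", length(srcs)), rep("sink", length(snks)))
    ref <- c(ref, ix$nodes[srcs], ix$nodes[snks])
  }
  A <- length(tail)
  arcs <- .pc_fast_df(tail = as.integer(tail), head = as.integer(head),
                      lower = as.integer(lower), cap = rep(Inf, A),
                      cost = numeric(A), kind = kind, ref = ref)
  flow_network(node_names, arcs, s = 1L, t = 2L)
}

#' Build the min-cost circulation network for weighted covers
#'
#' Same node-splitting as [build_minflow_network()], plus: split arcs carry a
#' per-node cost (used for subdivision midpoints standing for a required edge
#' or a subpath constraint), original edges carry their weight as cost, the
#' global source feeds exactly the nodes of `starts` and the global sink
#' drains exactly the nodes of `ends`, and a circulation arc `(t, s)` with
#' cost strictly exceeding any single path's weight makes every min-cost
#' circulation simultaneously a min-flow (path count is minimized first,
#' weight second).
#'
#' @param dag a `pc_dag` (the transformed graph, for the constrained problem).
#' @param required character vector of required nodes.
#' @param starts,ends character node sets `S`, `T`.
#' @param node_cost named numeric vector of split-arc costs (missing = 0).
#' @return a `pc_flownet` with the circulation arc set.
#' @export
build_mincost_network <- function(dag, required = dag$nodes,
                                  starts = sources_of(dag),
                                  ends = sinks_of(dag),
                                  node_cost = NULL) {
  ix <- .pc_index(dag)
  n <- ix$n
  node_names <- c("s", "t", paste0("in:", ix$nodes), paste0("out:", ix$nodes))
  inn <- function(v) 2L + v
  outn <- function(v) 2L + n + v
  req <- ix$nodes %in% as.character(required)
  ncost <- numeric(n)
  if (!is.null(node_cost) && length(node_cost)) {
    hit <- match(names(node_cost), ix$nodes)
    ncost[hit[!is.na(hit)]] <- node_cost[!is.na(hit)]
  }
  tail <- inn(seq_len(n)); head <- outn(seq_len(n))
  lower <- as.integer(req); cost <- ncost
  kind <- rep("node", n); ref <- ix$nodes
  if (length(ix$from_i)) {
    tail <- c(tail, outn(ix$from_i)); head <- c(head, inn(ix$to_i))
    lower <- c(lower, integer(length(ix$from_i)))
    cost <- c(cost, dag$edges$weight)
    kind <- c(kind, rep("edge", length(ix$from_i)))
    ref <- c(ref, paste(dag$edges$from, dag$edges$to, sep = "\r"))
  }
  si <- unname(ix$id[as.character(starts)])
  ti <- unname(ix$id[as.character(ends)])
  tail <- c(tail, rep(1L, length(si)), outn(ti))
  head <- c(head, inn(si), rep(2L, length(ti)))
  lower <- c(lower, integer(length(si) + length(ti)))
  cost <- c(cost, numeric(length(si) + length(ti)))
  kind <- c(kind, rep("source", length(si)), rep("sink", length(ti)))
  ref <- c(ref, ix$nodes[si], ix$nodes[ti])
  W <- sum(dag$edges$weight) + sum(ncost)
  tail <- c(tail, 2L); head <- c(head, 1L)
  lower <- c(lower, 0L); cost <- c(cost, W + 1)
  kind <- c(kind, "circ"); ref <- c(ref, NA_character_)
  A <- length(tail)
  arcs <- .pc_fast_df(tail = as.integer(tail), head = as.integer(head),
                      lower = as.integer(lower), cap = rep(Inf, A),
                      cost = cost, kind = kind, ref = ref)
  flow_network(node_names, arcs, s = 1L, t = 2L, circ = nrow(arcs))
}

#' Decompose a flow into source-to-sink paths
#'
#' The circulation arc (if any) is dropped; the remaining s-t flow on the DAG
#' is peeled into exactly `value` unit paths by repeatedly walking positive
#' arcs from `s` to `t` (deterministic: at each node the arc whose head has
#' the lexicographically smallest name, then lowest arc index). The arc-use
#' counts of the returned paths reproduce the flow exactly.
#'
#' @param fl a `pc_flow` as returned by [min_flow()] or
#'   [min_cost_circulation()].
#' @return list with `paths` (each a character vector of original node IDs,
#'   read off the `kind == "node"` arcs) and `arc_paths` (arc index
#'   sequences).
#' @export
decompose_flow_to_paths <- function(fl) {
  net <- fl$net
  arcs <- net$arcs
  flow <- fl$flow
  if (!is.na(net$circ)) flow[net$circ] <- 0
  # conservation sanity check at every node except s, t
  nnode <- length(net$node_names)
  bal <- numeric(nnode)
  for (i in seq_len(nrow(arcs))) {
    bal[arcs$tail[i]] <- bal[arcs$tail[i]] - flow[i]
    bal[arcs$head[i]] <- bal[arcs$head[i]] + flow[i]
  }
  inner <- setdiff(seq_len(nnode), c(net$s, net$t))
  if (any(abs(bal[inner]) > 1e-9)) {
    pc_decomposition_error("flow violates conservation; cannot decompose")
  }
  adj <- vector("list", nnode)
  grp <- split(seq_len(nrow(arcs)), arcs$tail)
  adj[as.integer(names(grp))] <- grp
  # deterministic pick order: by head-node name, then arc index
  for (v in seq_along(adj)) {
    if (length(adj[[v]]) > 1L) {
      aa <- adj[[v]]
      adj[[v]] <- aa[order(net$node_names[arcs$head[aa]], aa, method = "radix")]
    }
  }
  paths <- list()
  arc_paths <- list()
  repeat {
    v <- net$s
    seqa <- integer()
    while (v != net$t) {
      nxt <- NA_integer_
      for (aid in adj[[v]]) {
        if (flow[aid] > 1e-9) { nxt <- aid; break }
      }
      if (is.na(nxt)) {
        if (v == net$s && length(seqa) == 0L) break  # flow exhausted
        pc_decomposition_error("stuck while peeling a path; corrupt flow")
      }
      flow[nxt] <- flow[nxt] - 1
      seqa <- c(seqa, nxt)
      v <- arcs$head[nxt]
    }
    if (length(seqa) == 0L) break
    arc_paths[[length(arc_paths) + 1L]] <- seqa
    nodes <- arcs$ref[seqa][arcs$kind[seqa] == "node"]
    paths[[length(paths) + 1L]] <- nodes
  }
  list(paths = paths, arc_paths = arc_paths)
}
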