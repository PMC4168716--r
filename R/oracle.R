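# Independent oracles used as ground truth in tests: the classical bipartite
# matching reduction for MPC, brute-force maximum antichains, and exhaustive
# cover enumeration for the constrained problems. These deliberately share no
# machinery with the flow engines.

#' Minimum path cover via bipartite matching
#'
#' The classical construction: build a bipartite graph with two copies of the
#' node set and an edge between the first copy of `u` and the second copy of
#' `v` whenever a directed `u -> v` path exists; a maximum matching of size
#' `|M|` chains nodes into `n - |M|` cover paths. Matching is computed by
#' plain augmenting-path search; matched transitive edges are expanded through
#' closure witnesses so the output paths live in the input graph.
#'
#' @param dag a `pc_dag`.
#' @return a `pc_cover` with `problem = "mpc"`.
#' @export
mpc_by_matching <- function(dag) {
  ix <- .pc_index(dag)
  n <- ix$n
  if (n == 0L) return(cover_solution(list(), dag, "mpc", satisfied = TRUE))
  R <- .pc_reach_idx(ix)
  # right-neighbor lists in lexicographic order (deterministic augmentation)
  lexorder <- order(ix$rank)
  nbr <- lapply(seq_len(n), function(u) {
    vs <- lexorder[R[u, lexorder]]
    vs[vs != u]
  })
  match_r <- integer(n)  # right v -> left partner (0 = unmatched)
  match_l <- integer(n)
  for (u0 in seq_len(n)) {
    seen <- new.env()
    seen$s <- logical(n)
    aug <- function(u) {
      for (v in nbr[[u]]) {
        if (seen$s[v]) next
        seen$s[v] <- TRUE
        if (match_r[v] == 0L || aug(match_r[v])) {
          match_r[v] <<- u
          match_l[u] <<- v
          return(TRUE)
        }
      }
      FALSE
    }
    aug(u0)
  }
  # chain matched pairs into paths over closure edges; expand each matched
  # (transitive) edge through a concrete witness path of the input graph
  starts <- which(match_r == 0L)
  paths <- lapply(starts, function(s) {
    out <- s
    v <- s
    while (match_l[v] != 0L) {
      w <- match_l[v]
      out <- c(out, .pc_bfs_path(ix, v, w)[-1])
      v <- w
    }
    ix$nodes[out]
  })
  covered <- unique(unlist(paths))
  cover_solution(paths, dag, "mpc", satisfied = all(dag$nodes %in% covered))
}

#' Maximum antichain of a DAG
#'
#' A maximum-cardinality set of pairwise-unreachable nodes. For `n <= 20` the
#' set is found by branch-and-bound over independent sets of the
#' comparability graph (independent of any matching/flow machinery); for
#' larger graphs it is constructed from the matching oracle through the
#' standard minimum-vertex-cover argument.
#'
#' @param dag a `pc_dag`.
#' @return character vector of node IDs.
#' @export
max_antichain <- function(dag) {
  n <- length(dag$nodes)
  if (n == 0L) return(character())
  if (n > 2000L) pc_limit_error("max_antichain is limited to n <= 2000")
  if (n <= 20L) {
    R <- reachability(dag)
    comp <- (R | t(R)) & !diag(n)
    best <- integer()
    order_v <- seq_len(n)
    rec <- function(cand, cur) {
      if (length(cur) + length(cand) <= length(best)) return()
      if (!length(cand)) {
        if (length(cur) > length(best)) best <<- cur
        return()
      }
      v <- cand[1]
      rec(cand[-1][!comp[v, cand[-1]]], c(cur, v))  # include v
      rec(cand[-1], cur)                            # exclude v
    }
    rec(order_v, integer())
    return(dag$nodes[best])
  }
  .pc_antichain_konig(dag)
}

# antichain from the matching via Koenig's vertex-cover construction
.pc_antichain_konig <- function(dag) {
  R <- reachability(dag)
  nodes <- dag$nodes
  n <- length(nodes)
  adjL <- lapply(seq_len(n), function(u) which(R[u, ] & seq_len(n) != u))
  match_r <- integer(n)  # right v -> left partner (0 = unmatched)
  match_l <- integer(n)
  for (u0 in seq_len(n)) {
    seen_env <- new.env()
    seen_env$seen <- logical(n)
    aug <- function(u) {
      for (v in adjL[[u]]) {
        if (seen_env$seen[v]) next
        seen_env$seen[v] <- TRUE
        if (match_r[v] == 0L || aug(match_r[v])) {
          match_r[v] <<- u
          match_l[u] <<- v
          return(TRUE)
        }
      }
      FALSE
    }
    aug(u0)
  }
  # alternating reachability from unmatched left vertices
  Zl <- logical(n); Zr <- logical(n)
  queue <- which(match_l == 0L)
  Zl[queue] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adjL[[u]]) {
      if (match_l[u] == v) next  # matching edges not used left->right
      if (!Zr[v]) {
        Zr[v] <- TRUE
        w <- match_r[v]
        if (w != 0L && !Zl[w]) { Zl[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  # cover = (L not in Z) + (R in Z); antichain = nodes with neither copy covered
  pick <- Zl & !Zr
  nodes[pick]
}

#' Exhaustive minimum cover search (test oracle)
#'
#' Enumerates candidate paths (all maximal source-to-sink paths, or all
#' `S -> T` paths when start/end sets are posed) and searches subsets of
#' increasing size for one satisfying every constraint; with weights in force
#' the minimum-weight cover among minimum-cardinality ones is returned.
#' Exact by construction and exponential — for small instances only.
#'
#' @param inst a `pc_instance`.
#' @param k_max largest cover size tried (default: number of constraints).
#' @param weighted minimize weight among minimum covers (default: auto — on
#'   when any edge weight is nonzero or `S`/`T` are posed).
#' @param max_candidates,max_combos enumeration budgets; exceeding them raises
#'   `pc_limit_error`.
#' @return a `pc_cover`, or `NULL` when no cover of size `<= k_max` exists.
#' @export
brute_force_cover <- function(inst, k_max = NULL, weighted = NULL,
                              max_candidates = 2000L, max_combos = 2e6) {
  dag <- inst$dag
  ix <- .pc_index(dag)
  restricted <- !is.null(inst$starts)
  if (is.null(weighted)) weighted <- restricted || any(dag$edges$weight != 0)
  from_set <- if (restricted) unname(ix$id[inst$starts]) else
    which(tabulate(ix$to_i, nbins = ix$n) == 0L)
  is_end <- logical(ix$n)
  if (restricted) is_end[unname(ix$id[inst$ends])] <- TRUE else
    is_end[tabulate(ix$from_i, nbins = ix$n) == 0L] <- TRUE
  cands <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (is_end[v]) {
      if (restricted || length(ix$adj_out[[v]]) == 0L) {
        cands[[length(cands) + 1L]] <<- path
      }
    }
    for (w in ix$adj_out[[v]]) dfs(c(path, w))
    if (length(cands) > max_candidates) {
      pc_limit_error("too many candidate paths for exhaustive search")
    }
  }
  for (s in sort(from_set)) dfs(s)
  cands <- lapply(cands, function(p) ix$nodes[p])
  np <- length(cands)
  # constraint atoms and the path-satisfies-atom matrix
  atoms <- constraint_atoms(inst)
  na <- length(atoms)
  if (na == 0L) return(cover_solution(list(), dag, "oracle", satisfied = TRUE))
  sat <- matrix(FALSE, np, na)
  for (i in seq_len(np)) {
    for (j in seq_len(na)) {
      sat[i, j] <- all(vapply(atoms[[j]]$subpaths, .pc_is_contiguous,
                              TRUE, haystack = cands[[i]]))
    }
  }
  if (any(colSums(sat) == 0L)) return(NULL)  # some constraint unsatisfiable
  wts <- vapply(cands, function(p) path_weight(dag, p), 0)
  if (is.null(k_max)) k_max <- na
  k_max <- min(k_max, np)
  for (k in 0:k_max) {
    if (k == 0L) next  # na >= 1 here
    if (choose(np, k) > max_combos) {
      pc_limit_error("combination budget exceeded in exhaustive search")
    }
    combos <- utils::combn(np, k)
    best <- NULL
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      if (all(.colSums(sat[idx, , drop = FALSE], k, na) > 0L)) {
        w <- sum(wts[idx])
        if (!weighted) {
          best <- idx
          break
        }
        if (is.null(best) || w < sum(wts[best]) - 1e-9) best <- idx
      }
    }
    if (!is.null(best)) {
      return(cover_solution(cands[best], dag, "oracle", satisfied = TRUE))
    }
  }
  NULL
}
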