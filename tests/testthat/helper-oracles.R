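# Independent brute-force oracles and graph builders for the test suite.
# These deliberately avoid the package's internal machinery: reachability by
# boolean matrix powers, path enumeration by plain DFS over an edge list,
# coloring by exhaustive assignment.

diamond_dag <- function(weights = NULL) {
  e <- list(c("1", "2"), c("1", "3"), c("2", "4"), c("3", "4"))
  if (!is.null(weights)) e <- Map(function(p, w) c(p, w), e, weights)
  dag(as.character(1:4), e)
}

chain_dag <- function(n) {
  nodes <- as.character(seq_len(n))
  if (n == 1L) return(dag(nodes))
  dag(nodes, data.frame(from = nodes[-n], to = nodes[-1]))
}

# all labeled DAGs on n nodes with edges going from lower to higher label
# (covers every DAG up to relabeling)
enumerate_dags <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  lapply(0:(2^np - 1L), function(mask) {
    sel <- bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0
    em <- pairs[sel, , drop = FALSE]
    dag(as.character(seq_len(n)),
        if (nrow(em)) data.frame(from = as.character(em[, 1]),
                                 to = as.character(em[, 2])) else NULL)
  })
}

random_test_dag <- function(n, p = 0.3) {
  em <- which(upper.tri(matrix(0, n, n)) & matrix(runif(n * n), n, n) < p,
              arr.ind = TRUE)
  dag(as.character(seq_len(n)),
      if (nrow(em)) data.frame(from = as.character(em[, 1]),
                               to = as.character(em[, 2])) else NULL)
}

# reachability oracle: reflexive closure via boolean matrix powers
brute_reach <- function(d) {
  n <- length(d$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(d$nodes, d$nodes))
  if (nrow(d$edges)) A[cbind(d$edges$from, d$edges$to)] <- TRUE
  R <- diag(n) > 0
  dimnames(R) <- dimnames(A)
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# all topological orders by recursive enumeration
brute_topo_orders <- function(d) {
  nodes <- d$nodes
  out <- list()
  rec <- function(placed, remaining) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- placed
      return(invisible())
    }
    for (v in remaining) {
      preds <- d$edges$from[d$edges$to == v]
      if (all(!(preds %in% remaining))) rec(c(placed, v), setdiff(remaining, v))
    }
  }
  rec(character(), nodes)
  out
}

# all simple directed paths between two nodes (plain DFS on the edge list)
brute_paths_between <- function(d, from, to) {
  out <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in d$edges$to[d$edges$from == v]) rec(c(path, w))
  }
  rec(from)
  out
}

# all maximal (source-to-sink) paths
brute_maximal_paths <- function(d) {
  srcs <- setdiff(d$nodes, d$edges$to)
  snks <- setdiff(d$nodes, d$edges$from)
  out <- list()
  for (s in srcs) {
    for (t in snks) out <- c(out, brute_paths_between(d, s, t))
  }
  out
}

# maximum antichain size by subset enumeration on the reachability oracle
brute_antichain_size <- function(d) {
  n <- length(d$nodes)
  if (n == 0L) return(0L)
  R <- brute_reach(d)
  best <- 0L
  for (mask in 1:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    for (a in sel) for (b in sel) {
      if (a != b && R[a, b]) { ok <- FALSE; break }
    }
    if (ok) best <- length(sel)
  }
  best
}

contiguous_in <- function(haystack, needle) {
  nh <- length(haystack); nn <- length(needle)
  if (nn > nh) return(FALSE)
  for (s in 1:(nh - nn + 1L)) {
    if (all(haystack[s:(s + nn - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

# exhaustive minimum constrained cover, independent of the package oracle:
# candidates = all maximal paths (or all S->T paths), atoms checked directly
brute_min_cover <- function(inst, k_max = 5L) {
  d <- inst$dag
  if (!is.null(inst$starts)) {
    cands <- list()
    for (s in inst$starts) {
      rec <- function(path) {
        v <- path[length(path)]
        if (v %in% inst$ends) cands[[length(cands) + 1L]] <<- path
        for (w in d$edges$to[d$edges$from == v]) rec(c(path, w))
      }
      rec(s)
    }
  } else {
    cands <- brute_maximal_paths(d)
  }
  sat_atom <- function(path, atom) {
    all(vapply(atom, function(sp) contiguous_in(path, sp), TRUE))
  }
  atoms <- c(lapply(inst$required_nodes, function(v) list(v)),
             if (nrow(inst$required_edges)) lapply(seq_len(nrow(inst$required_edges)),
               function(i) list(c(inst$required_edges$from[i], inst$required_edges$to[i]))),
             lapply(inst$subpaths, function(p) list(p)),
             lapply(inst$pairs, function(pr) pr))
  if (!length(atoms)) return(list(k = 0L, weight = 0))
  pw <- vapply(cands, function(p) {
    if (length(p) < 2L) return(0)
    sum(vapply(seq_len(length(p) - 1L), function(i) {
      d$edges$weight[d$edges$from == p[i] & d$edges$to == p[i + 1L]]
    }, 0))
  }, 0)
  np <- length(cands)
  for (k in 1:min(k_max, np)) {
    combos <- utils::combn(np, k)
    best_w <- NULL
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      ok <- all(vapply(atoms, function(a) {
        any(vapply(idx, function(i) sat_atom(cands[[i]], a), TRUE))
      }, TRUE))
      if (ok) {
        w <- sum(pw[idx])
        if (is.null(best_w) || w < best_w - 1e-9) best_w <- w
      }
    }
    if (!is.null(best_w)) return(list(k = k, weight = best_w))
  }
  NULL
}

# exhaustive chromatic number by trying every assignment
brute_chromatic <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  if (!any(adj)) return(1L)
  for (k in 2:n) {
    colors <- rep(1L, n)
    repeat {
      ok <- TRUE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (adj[i, j] && colors[i] == colors[j]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) return(k)
      # next assignment in base k
      i <- 1L
      while (i <= n) {
        colors[i] <- colors[i] + 1L
        if (colors[i] <= k) break
        colors[i] <- 1L
        i <- i + 1L
      }
      if (i > n) break
    }
  }
  n
}

# random constrained instance: subpaths sampled as windows of maximal paths,
# so every constraint is satisfiable
random_sc_instance <- function(n = 8L, max_subpaths = 3L, p = 0.35,
                               weighted = FALSE, with_st = FALSE) {
  repeat {
    d <- random_test_dag(n, p)
    mp <- brute_maximal_paths(d)
    if (length(mp) >= 1L && length(mp) <= 40L) break
  }
  if (weighted) {
    d <- dag(d$nodes, d$edges[, c("from", "to")],
             weights = sample(0:5, nrow(d$edges), replace = TRUE))
  }
  ns <- sample.int(max_subpaths + 1L, 1L) - 1L
  subpaths <- list()
  for (i in seq_len(ns)) {
    p0 <- mp[[sample.int(length(mp), 1L)]]
    if (length(p0) < 2L) next
    L <- sample(2:min(4L, length(p0)), 1L)
    s <- sample.int(length(p0) - L + 1L, 1L)
    subpaths[[length(subpaths) + 1L]] <- p0[s:(s + L - 1L)]
  }
  req <- sample(d$nodes, sample.int(length(d$nodes), 1L))
  if (with_st) {
    starts <- union(setdiff(d$nodes, d$edges$to),
                    sample(d$nodes, sample.int(2L, 1L) - 1L))
    ends <- union(setdiff(d$nodes, d$edges$from),
                  sample(d$nodes, sample.int(2L, 1L) - 1L))
    instance(d, required_nodes = req, subpaths = subpaths,
             starts = starts, ends = ends)
  } else {
    instance(d, required_nodes = req, subpaths = subpaths)
  }
}
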