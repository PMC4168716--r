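# Synthetic data: splicing-graph-like DAGs with ground-truth transcripts,
# long-read and paired-end constraint samplers, the NP-hardness gadget built
# from 3-colorability, and the overlap-chain family on which the incomplete
# (no-merge) reduction fails.

#' Simulation parameters for the splicing-graph generator
#'
#' Defaults describe a desk-scale gene: 20 pseudo-exons, 3 expressed
#' transcripts each containing roughly half the exons, 10 error-free long
#' reads spanning 4 consecutive pseudo-exons, 5 read pairs with a mate gap of
#' 1-3 pseudo-exons.
#'
#' @param num_exons number of pseudo-exons (nodes), ordered along the gene.
#' @param num_transcripts number of ground-truth transcript paths.
#' @param edge_density probability that a transcript contains a given exon.
#' @param read_length long-read span in pseudo-exons (>= 2).
#' @param num_long_reads number of sampled subpath constraints.
#' @param num_pairs number of sampled paired constraints.
#' @param gap_range integer range (min, max) of the mate gap in pseudo-exons.
#' @param seed integer seed; identical parameters give identical instances.
#' @return list of class `pc_simparams`.
#' @export
simulation_params <- function(num_exons = 20L, num_transcripts = 3L,
                              edge_density = 0.5, read_length = 4L,
                              num_long_reads = 10L, num_pairs = 5L,
                              gap_range = c(1L, 3L), seed = 1L) {
  if (num_exons < 2L || num_transcripts < 1L) {
    pc_validation_error("need at least 2 exons and 1 transcript")
  }
  if (edge_density <= 0 || edge_density > 1) {
    pc_validation_error("edge_density must lie in (0, 1]")
  }
  if (read_length < 2L) pc_validation_error("read_length must be >= 2")
  if (num_long_reads < 0L || num_pairs < 0L) {
    pc_validation_error("read counts must be non-negative")
  }
  structure(list(num_exons = as.integer(num_exons),
                 num_transcripts = as.integer(num_transcripts),
                 edge_density = edge_density,
                 read_length = as.integer(read_length),
                 num_long_reads = as.integer(num_long_reads),
                 num_pairs = as.integer(num_pairs),
                 gap_range = as.integer(gap_range),
                 seed = as.integer(seed)),
            class = "pc_simparams")
}

#' Generate a random splicing-graph DAG with ground-truth transcripts
#'
#' Nodes are ordered pseudo-exons `1..num_exons`; each transcript is an
#' increasing subsequence of exons (each exon included with probability
#' `edge_density`, at least two per transcript) and contributes its
#' consecutive exon pairs as edges. Every exon is patched onto at least one
#' transcript, so the transcripts form a path cover and the graph is acyclic
#' by construction.
#'
#' @param params a `pc_simparams`.
#' @return list with `dag` (a `pc_dag`, weight 0 edges) and `transcripts`
#'   (list of node sequences, each a valid path).
#' @export
random_splicing_dag <- function(params = simulation_params()) {
  withr::with_seed(params$seed, {
    E <- params$num_exons
    tx <- lapply(seq_len(params$num_transcripts), function(i) {
      keep <- which(stats::runif(E) < params$edge_density)
      while (length(keep) < 2L) {
        keep <- sort(unique(c(keep, sample.int(E, 1L))))
      }
      keep
    })
    uncovered <- setdiff(seq_len(E), unique(unlist(tx)))
    for (v in uncovered) {
      i <- sample.int(params$num_transcripts, 1L)
      tx[[i]] <- sort(unique(c(tx[[i]], v)))
    }
    tx <- lapply(tx, as.character)
    edges <- unique(do.call(rbind, lapply(tx, function(p) {
      if (length(p) < 2L) return(NULL)
      cbind(p[-length(p)], p[-1])
    })))
    g <- dag(as.character(seq_len(E)), edges)
    list(dag = g, transcripts = tx)
  })
}

#' Sample long-read subpath constraints from transcripts
#'
#' Each read is a contiguous window of `read_length` pseudo-exons from a
#' uniformly chosen transcript (the whole transcript when it is shorter), so
#' every sampled constraint is a valid path satisfiable by its ground truth.
#'
#' @param sim output of [random_splicing_dag()].
#' @param params a `pc_simparams` (uses `num_long_reads`, `read_length`,
#'   `seed`).
#' @return list of node sequences.
#' @export
sample_long_reads <- function(sim, params = simulation_params()) {
  if (params$num_long_reads == 0L) return(list())
  withr::with_seed(params$seed + 1L, {
    lapply(seq_len(params$num_long_reads), function(i) {
      p <- sim$transcripts[[sample.int(length(sim$transcripts), 1L)]]
      L <- min(params$read_length, length(p))
      s <- sample.int(length(p) - L + 1L, 1L)
      p[s:(s + L - 1L)]
    })
  })
}

#' Sample paired-end constraints from transcripts
#'
#' Each pair consists of two disjoint windows of the same transcript
#' separated by a gap drawn from `gap_range`; windows shrink on short
#' transcripts (down to single exons) so every pair is individually feasible
#' by construction.
#'
#' @param sim output of [random_splicing_dag()].
#' @param params a `pc_simparams` (uses `num_pairs`, `read_length`,
#'   `gap_range`, `seed`).
#' @return list of pairs (each a list of two node sequences).
#' @export
sample_paired_reads <- function(sim, params = simulation_params()) {
  if (params$num_pairs == 0L) return(list())
  withr::with_seed(params$seed + 2L, {
    lapply(seq_len(params$num_pairs), function(i) {
      p <- sim$transcripts[[sample.int(length(sim$transcripts), 1L)]]
      len <- length(p)
      gaps <- seq(params$gap_range[1], params$gap_range[2])
      gap <- gaps[sample.int(length(gaps), 1L)]
      gap <- min(gap, max(0L, len - 2L))
      w <- min(params$read_length, (len - gap) %/% 2L)
      w <- max(w, 1L)
      smax <- len - (2L * w + gap) + 1L
      s1 <- if (smax >= 1L) sample.int(smax, 1L) else 1L
      s2 <- s1 + w + gap
      list(p[s1:(s1 + w - 1L)], p[s2:min(len, s2 + w - 1L)])
    })
  })
}

#' NP-hardness gadget: 3-colorability as paired-constraint path cover
#'
#' Builds the reduction DAG for an undirected graph `G` without isolated
#' vertices: a backbone `b0 -> ... -> b(n+m+1)`, a first stage of `n` blocks
#' (one per vertex, three parallel length-2 branches labeled `v_k`, `X_k`,
#' `Y_k`), a second stage of `m` blocks (one per edge `{v_i, v_j}`, branches
#' labeled `[v_i]`, `[v_j]` and one unlabeled), and a tail edge. Paired
#' constraints tie every second-stage label `[v]` to the first-stage branch
#' of `v`, and every first-stage branch to the tail edge so that all three
#' branches of each block must be covered using paired constraints only. The
#' resulting instance admits a 3-path solution iff `G` is 3-colorable; for
#' non-bipartite `G` the optimum is never below 3.
#'
#' @param vertices character vector of vertex names of `G`.
#' @param edges list of 2-element vectors (undirected edges of `G`).
#' @return list with `instance` (a `pc_instance` with only paired
#'   constraints), `labels` (named list label -> branch path) and
#'   `source_graph`.
#' @export
hardness_gadget <- function(vertices, edges) {
  vertices <- as.character(vertices)
  edges <- lapply(edges, as.character)
  if (any(vapply(edges, length, 0L) != 2L)) {
    pc_gadget_error("each edge of the source graph must have two endpoints")
  }
  touched <- unique(unlist(edges))
  if (!all(vertices %in% touched)) {
    pc_gadget_error("source graph has isolated vertices")
  }
  if (.pc_is_bipartite_undirected(vertices, edges)) {
    pc_gadget_error("source graph is bipartite; the reduction requires a non-bipartite graph")
  }
  n <- length(vertices); m <- length(edges)
  bb <- paste0("b", 0:(n + m + 1L))
  nodes <- bb
  from <- character(); to <- character()
  labels <- list()
  add_branch <- function(mid, left, right) {
    nodes <<- c(nodes, mid)
    from <<- c(from, left, mid)
    to <<- c(to, mid, right)
    c(left, mid, right)
  }
  # first stage: one block per vertex, branches v_k, X_k, Y_k
  for (k in seq_len(n)) {
    v <- vertices[k]
    labels[[paste0("v:", v)]] <- add_branch(paste0("mv.", v), bb[k], bb[k + 1L])
    labels[[paste0("X:", k)]] <- add_branch(paste0("mx.", k), bb[k], bb[k + 1L])
    labels[[paste0("Y:", k)]] <- add_branch(paste0("my.", k), bb[k], bb[k + 1L])
  }
  # second stage: one block per edge, branches [v_i], [v_j] and an unlabeled one
  for (k in seq_len(m)) {
    e <- edges[[k]]
    left <- bb[n + k]; right <- bb[n + k + 1L]
    labels[[paste0("ref:", k, ":", e[1])]] <- add_branch(paste0("mp.", k, ".", e[1]), left, right)
    labels[[paste0("ref:", k, ":", e[2])]] <- add_branch(paste0("mp.", k, ".", e[2]), left, right)
    add_branch(paste0("mq.", k), left, right)  # unlabeled free branch
  }
  tail_path <- c(bb[n + m + 1L], bb[n + m + 2L])
  from <- c(from, tail_path[1])
  to <- c(to, tail_path[2])
  g <- dag(nodes, data.frame(from = from, to = to, stringsAsFactors = FALSE))
  pairs <- list()
  for (k in seq_len(m)) {
    e <- edges[[k]]
    pairs[[length(pairs) + 1L]] <- list(labels[[paste0("v:", e[1])]],
                                        labels[[paste0("ref:", k, ":", e[1])]])
    pairs[[length(pairs) + 1L]] <- list(labels[[paste0("v:", e[2])]],
                                        labels[[paste0("ref:", k, ":", e[2])]])
  }
  for (k in seq_len(n)) {
    pairs[[length(pairs) + 1L]] <- list(labels[[paste0("v:", vertices[k])]], tail_path)
    pairs[[length(pairs) + 1L]] <- list(labels[[paste0("X:", k)]], tail_path)
    pairs[[length(pairs) + 1L]] <- list(labels[[paste0("Y:", k)]], tail_path)
  }
  inst <- instance(g, pairs = pairs)
  list(instance = inst, labels = labels,
       source_graph = list(vertices = vertices, edges = edges))
}

.pc_is_bipartite_undirected <- function(vertices, edges) {
  col <- stats::setNames(rep(NA_integer_, length(vertices)), vertices)
  nbr <- stats::setNames(vector("list", length(vertices)), vertices)
  for (e in edges) {
    nbr[[e[1]]] <- c(nbr[[e[1]]], e[2])
    nbr[[e[2]]] <- c(nbr[[e[2]]], e[1])
  }
  for (s in vertices) {
    if (!is.na(col[s])) next
    col[s] <- 0L
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (w in nbr[[u]]) {
        if (is.na(col[w])) {
          col[w] <- 1L - col[u]
          queue <- c(queue, w)
        } else if (col[w] == col[u]) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Named small graphs for the hardness gadget
#'
#' Convenience constructors: `"k3"` (triangle), `"c5"` (5-cycle, chromatic
#' number 3), `"k4"` (complete graph on 4 vertices, chromatic number 4).
#'
#' @param name one of `"k3"`, `"c5"`, `"k4"`.
#' @return list with `vertices` and `edges` suitable for [hardness_gadget()].
#' @export
named_source_graph <- function(name) {
  switch(tolower(name),
    k3 = list(vertices = c("a", "b", "c"),
              edges = list(c("a", "b"), c("b", "c"), c("a", "c"))),
    c5 = list(vertices = paste0("u", 1:5),
              edges = list(c("u1", "u2"), c("u2", "u3"), c("u3", "u4"),
                           c("u4", "u5"), c("u5", "u1"))),
    k4 = list(vertices = c("a", "b", "c", "d"),
              edges = list(c("a", "b"), c("a", "c"), c("a", "d"),
                           c("b", "c"), c("b", "d"), c("c", "d"))),
    pc_validation_error(sprintf("unknown named graph '%s'", name))
  )
}

#' Overlap-chain fixture family
#'
#' A chain DAG `1 -> ... -> depth+2` with subpath constraints
#' `P_i = (i, i+1, i+2)` for `i = 1..depth` and all nodes required.
#' Consecutive constraints share a 2-node suffix/prefix overlap and
#' non-consecutive ones share shorter overlaps — exactly the configuration a
#' reduction without containment removal and longest-first merging
#' mishandles: the full pipeline covers the chain with one path while the
#' naive variant needs `depth` paths.
#'
#' @param depth number of overlapping constraints (>= 2).
#' @return a `pc_instance`.
#' @export
overlap_chain_fixture <- function(depth) {
  if (depth < 2L) pc_validation_error("depth must be >= 2")
  L <- depth + 2L
  nodes <- as.character(seq_len(L))
  g <- dag(nodes, data.frame(from = nodes[-L], to = nodes[-1],
                             stringsAsFactors = FALSE))
  sp <- lapply(seq_len(depth), function(i) nodes[i:(i + 2L)])
  instance(g, required_nodes = nodes, subpaths = sp)
}
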