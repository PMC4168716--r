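# The reduction from subpath-constrained path cover to classical MPC:
# constraint normalization, containment removal, longest-first suffix/prefix
# merging, shortcut-edge modelling with midpoint subdivision, transitive
# closure restricted to the required set, and the reverse lifting of reduced
# covers. A ReductionTrace records every transformation so solutions can be
# mapped back and re-verified against the untouched input.

#' Normalize node and edge constraints against subpath constraints
#'
#' Drops from `V'` every endpoint of a required edge (a path covering the
#' edge covers both endpoints), and drops from `V'`/`E'` every node/edge
#' lying on a subpath constraint (covering the subpath covers them).
#' Degenerate single-node subpaths are moved into `V'` and removed from the
#' subpath family, so that later merging only ever sees paths with at least
#' one edge.
#'
#' @param inst a `pc_instance`.
#' @return a `pc_instance` with reduced constraint sets (same DAG).
#' @export
normalize_constraints <- function(inst) {
  vp <- inst$required_nodes
  ep <- inst$required_edges
  sp <- inst$subpaths
  singles <- vapply(sp, length, 0L) == 1L
  vp <- unique(c(vp, unlist(sp[singles])))
  sp <- sp[!singles]
  if (length(sp)) {
    on_nodes <- unique(unlist(sp))
    on_edges <- unique(unlist(lapply(sp, function(p) {
      if (length(p) < 2L) character() else paste(p[-length(p)], p[-1], sep = "\r")
    })))
    vp <- setdiff(vp, on_nodes)
    if (nrow(ep)) ep <- ep[!(paste(ep$from, ep$to, sep = "\r") %in% on_edges), , drop = FALSE]
  }
  if (nrow(ep)) vp <- setdiff(vp, unique(c(ep$from, ep$to)))
  instance(inst$dag, required_nodes = vp, required_edges = ep, subpaths = sp,
           pairs = inst$pairs, starts = inst$starts, ends = inst$ends)
}

#' Remove subpath constraints contained in another
#'
#' A subpath that appears as a contiguous subsequence of another carries no
#' extra information. Exact duplicates are reduced to the copy with the
#' lowest index.
#'
#' @param subpaths list of node sequences.
#' @return the filtered list.
#' @export
remove_contained_subpaths <- function(subpaths) {
  ns <- length(subpaths)
  if (ns < 2L) return(subpaths)
  drop <- logical(ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      if (identical(subpaths[[i]], subpaths[[j]])) {
        if (j < i) { drop[i] <- TRUE; break }
      } else if (.pc_is_contiguous(subpaths[[j]], subpaths[[i]])) {
        drop[i] <- TRUE; break
      }
    }
  }
  subpaths[!drop]
}

#' Longest suffix-prefix overlap of two paths
#'
#' The largest `len >= 1` such that the last `len` nodes of `p` equal the
#' first `len` nodes of `q`, or 0 when no suffix of `p` is a prefix of `q`.
#' Computed by direct comparison.
#'
#' @param p,q node sequences (distinct, neither containing the other).
#' @return integer overlap length.
#' @export
longest_suffix_prefix_overlap <- function(p, q) {
  p <- as.character(p); q <- as.character(q)
  np <- length(p); nq <- length(q)
  for (len in seq.int(min(np, nq), 1L)) {
    if (identical(p[(np - len + 1L):np], q[1:len])) return(len)
  }
  0L
}

#' Iteratively merge subpath constraints sharing a suffix/prefix
#'
#' While any ordered pair of constraints overlaps (a suffix of one equals a
#' prefix of the other), the pair with the longest overlap is merged into
#' their union, which starts as the first and ends as the second. Ties are
#' broken by smallest first index, then smallest second index. After the loop
#' the containment filter is re-run as a defensive invariant check: it must
#' remove nothing, otherwise a `pc_merge_error` is raised.
#'
#' @param subpaths list of node sequences (already containment-free).
#' @param dag optional `pc_dag`; when given, each merged sequence is checked
#'   to still be a valid path (a failure indicates corrupted state and raises
#'   `pc_merge_error`).
#' @return list with `subpaths` (the merged family) and `merges` (log of
#'   `list(i, j, len, merged)` records, in merge order).
#' @export
merge_subpaths_iteratively <- function(subpaths, dag = NULL) {
  sp <- lapply(subpaths, as.character)
  log <- list()
  repeat {
    ns <- length(sp)
    best <- NULL
    if (ns >= 2L) {
      for (i in seq_len(ns)) {
        for (j in seq_len(ns)) {
          if (i == j) next
          len <- longest_suffix_prefix_overlap(sp[[i]], sp[[j]])
          if (len >= 1L && (is.null(best) || len > best$len)) {
            best <- list(i = i, j = j, len = len)
          }
        }
      }
    }
    if (is.null(best)) break
    pi <- sp[[best$i]]; pj <- sp[[best$j]]
    merged <- c(pi, pj[(best$len + 1L):length(pj)])
    if (!is.null(dag) && !is_path(dag, merged)) {
      pc_merge_error(sprintf("merged constraint (%s) is not a valid path",
                             paste(merged, collapse = ",")))
    }
    log[[length(log) + 1L]] <- list(i = best$i, j = best$j, len = best$len,
                                    merged = merged)
    sp[[best$i]] <- merged
    sp[[best$j]] <- NULL
  }
  after <- remove_contained_subpaths(sp)
  if (length(after) != length(sp)) {
    pc_merge_error("merging created a containment between constraints; corrupted state")
  }
  list(subpaths = sp, merges = log)
}

#' Model subpath constraints as (possibly parallel) shortcut edges
#'
#' Each remaining subpath constraint from `s` to `t` contributes a new edge
#' `(s, t)` to a transient multigraph; the new edge joins the edge-constraint
#' set and the shortcut map remembers which subpath it stands for. Parallel
#' edges are permitted here — the subsequent subdivision turns them into
#' parallel length-2 paths and the graph becomes simple again.
#'
#' @param dag a `pc_dag`.
#' @param subpaths list of node sequences (merged, containment-free).
#' @return list with `graph` (data.frame `from`, `to`, `weight`, `id`; ids
#'   `e<k>` for original edges, `c<k>` for shortcuts), `econ_add` (ids of the
#'   new constraint edges) and `shortcut` (named list id -> subpath).
#' @export
subpaths_to_edge_constraints <- function(dag, subpaths) {
  ed <- dag$edges
  g <- data.frame(from = ed$from, to = ed$to, weight = ed$weight,
                  id = if (nrow(ed)) paste0("e", seq_len(nrow(ed))) else character(),
                  stringsAsFactors = FALSE)
  shortcut <- list()
  econ_add <- character()
  for (k in seq_along(subpaths)) {
    p <- subpaths[[k]]
    id <- paste0("c", k)
    g <- rbind(g, data.frame(from = p[1], to = p[length(p)], weight = 0,
                             id = id, stringsAsFactors = FALSE))
    shortcut[[id]] <- p
    econ_add <- c(econ_add, id)
  }
  list(graph = g, econ_add = econ_add, shortcut = shortcut)
}

#' Subdivide constraint edges into required midpoints
#'
#' Every edge-constraint `e = (u, v)` of the multigraph is replaced by a fresh
#' midpoint node `v_e` and edges `(u, v_e)`, `(v_e, v)`; the midpoint joins
#' the required node set. The midpoint map records whether `v_e` stands for an
#' original required edge (expansion `(u, v)`, carrying the edge's weight) or
#' for a subpath constraint (expansion = the full subpath, carrying the sum of
#' its edge weights). The result is a simple DAG again.
#'
#' @param graph multigraph data.frame as produced by
#'   [subpaths_to_edge_constraints()].
#' @param econ_ids ids of the edges to subdivide (original required edges
#'   and/or shortcut edges).
#' @param nodes character vector of the graph's declared nodes.
#' @param shortcut named list id -> subpath for shortcut edges.
#' @param orig_dag optional original `pc_dag` for computing subpath weights.
#' @return list with `dag` (the transformed simple `pc_dag`; half-edges have
#'   weight 0), `midpoints` (list of records `node`, `kind`, `from`, `to`,
#'   `expansion`, `weight`) and `vprime_add` (the midpoint node ids).
#' @export
subdivide_edge_constraints <- function(graph, econ_ids, nodes,
                                       shortcut = list(), orig_dag = NULL) {
  midpoints <- list()
  all_nodes <- nodes
  for (k in seq_along(econ_ids)) {
    id <- econ_ids[k]
    row <- which(graph$id == id)
    if (length(row) != 1L) pc_validation_error(sprintf("unknown constraint edge id %s", id))
    u <- graph$from[row]; v <- graph$to[row]; w <- graph$weight[row]
    mid <- paste0("m", length(midpoints) + 1L)
    while (mid %in% all_nodes) mid <- paste0("_", mid)
    all_nodes <- c(all_nodes, mid)
    is_sc <- id %in% names(shortcut)
    expansion <- if (is_sc) shortcut[[id]] else c(u, v)
    wgt <- if (is_sc) {
      if (is.null(orig_dag)) 0 else path_weight(orig_dag, expansion)
    } else w
    midpoints[[length(midpoints) + 1L]] <-
      list(node = mid, kind = if (is_sc) "subpath" else "edge",
           from = u, to = v, expansion = expansion, weight = wgt)
    graph <- graph[-row, , drop = FALSE]
    graph <- rbind(graph,
                   data.frame(from = c(u, mid), to = c(mid, v), weight = 0,
                              id = paste0(id, c(":a", ":b")),
                              stringsAsFactors = FALSE))
  }
  tdag <- dag(all_nodes, graph[, c("from", "to", "weight")])
  list(dag = tdag, midpoints = midpoints,
       vprime_add = vapply(midpoints, `[[`, "", "node"))
}

# Steps 1-6: shared by the unweighted (closure) and weighted (flow) routes.
.pc_transform16 <- function(inst, naive = FALSE) {
  norm <- normalize_constraints(inst)
  sp <- norm$subpaths
  contained_removed <- list()
  merges <- list()
  if (!naive) {
    kept <- remove_contained_subpaths(sp)
    contained_removed <- sp[!vapply(sp, function(p) {
      any(vapply(kept, identical, TRUE, x = p))
    }, TRUE)]
    mres <- merge_subpaths_iteratively(kept, dag = inst$dag)
    sp <- mres$subpaths
    merges <- mres$merges
  }
  s5 <- subpaths_to_edge_constraints(inst$dag, sp)
  orig_ids <- character()
  if (nrow(norm$required_edges)) {
    key_g <- paste(s5$graph$from, s5$graph$to, sep = "\r")
    key_e <- paste(norm$required_edges$from, norm$required_edges$to, sep = "\r")
    orig_ids <- s5$graph$id[match(key_e, key_g)]
  }
  econ_ids <- c(orig_ids, s5$econ_add)
  s6 <- subdivide_edge_constraints(s5$graph, econ_ids, nodes = inst$dag$nodes,
                                   shortcut = s5$shortcut, orig_dag = inst$dag)
  vprime <- c(norm$required_nodes, s6$vprime_add)
  list(original = inst, normalized = norm, naive = naive,
       contained_removed = contained_removed, merges = merges,
       merged_subpaths = sp, tdag = s6$dag, midpoints = s6$midpoints,
       vprime = vprime)
}

#' Reduce a subpath-constrained instance to a classical MPC instance
#'
#' Runs the full preprocessing pipeline: constraint normalization, containment
#' removal, longest-first suffix/prefix merging, shortcut-edge modelling with
#' midpoint subdivision, then replaces the transformed graph by its transitive
#' closure and induces it on the required node set. The returned trace holds
#' everything needed to lift a cover of the reduced graph back to the input.
#'
#' @param inst a `pc_instance` (no pairs; `S`/`T` not posed).
#' @param naive if `TRUE`, skip containment removal and merging (the
#'   incomplete reduction this pipeline corrects; exposed for testing only —
#'   on overlapping constraint families it yields strictly worse covers).
#' @return list with `reduced` (a `pc_dag` over the required set) and `trace`
#'   (class `pc_trace`).
#' @export
reduce_to_classic_mpc <- function(inst, naive = FALSE) {
  tr <- .pc_transform16(inst, naive = naive)
  cl <- transitive_closure(tr$tdag)
  keep <- intersect(cl$closure$nodes, tr$vprime)
  ed <- cl$closure$edges
  ed <- ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
  reduced <- dag(keep, ed)
  tr$witness <- cl$witness
  tr$reduced <- reduced
  class(tr) <- "pc_trace"
  list(reduced = reduced, trace = tr)
}

#' @export
print.pc_trace <- function(x, ...) {
  cat(sprintf(paste0("<pc_trace> %s pipeline: %d merge(s), %d midpoint(s), ",
                     "transformed graph %d nodes%s\n"),
              if (isTRUE(x$naive)) "naive" else "full",
              length(x$merges), length(x$midpoints), length(x$tdag$nodes),
              if (!is.null(x$reduced)) sprintf(", reduced graph %d nodes",
                                               length(x$reduced$nodes)) else ""))
  invisible(x)
}

# serialize a trace for debugging
trace_to_json <- function(tr, path) {
  doc <- list(naive = isTRUE(tr$naive),
              merges = lapply(tr$merges, function(m) {
                list(i = m$i, j = m$j, len = m$len, merged = as.list(m$merged))
              }),
              midpoints = lapply(tr$midpoints, function(m) {
                list(node = m$node, kind = m$kind,
                     expansion = as.list(m$expansion), weight = m$weight)
              }),
              vprime = as.list(tr$vprime))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# replace midpoint nodes by their expansions, collapsing the duplicated
# boundary nodes
.pc_expand_midpoints <- function(path, midpoints) {
  if (!length(midpoints)) return(path)
  exp_map <- stats::setNames(lapply(midpoints, `[[`, "expansion"),
                             vapply(midpoints, `[[`, "", "node"))
  out <- character()
  for (v in path) {
    piece <- if (!is.null(exp_map[[v]])) exp_map[[v]] else v
    out <- c(out, piece)
  }
  # collapse consecutive duplicates introduced at expansion boundaries
  if (length(out) > 1L) out <- out[c(TRUE, out[-1] != out[-length(out)])]
  out
}

#' Lift a cover of the reduced graph back to the original instance
#'
#' Reverts the reduction in reverse order: every edge of a reduced path is
#' expanded through its transitive-closure witness into a path of the
#' transformed graph, every midpoint node is expanded into the original
#' required edge or the full (merged) subpath it stands for, and the result is
#' re-verified against the original, untouched constraint sets.
#'
#' @param paths list of node sequences over the reduced graph.
#' @param trace a `pc_trace` from [reduce_to_classic_mpc()].
#' @param problem problem tag for the returned solution.
#' @param strict if `TRUE` (default) a verification failure raises
#'   `pc_lift_error`; if `FALSE` the unverified solution is returned with
#'   `satisfied = FALSE` (used to exhibit the naive pipeline's defect).
#' @return a `pc_cover` over the original DAG.
#' @export
lift_solution <- function(paths, trace, problem = "mpc-sc", strict = TRUE) {
  orig <- trace$original
  lifted <- lapply(paths, function(p) {
    p <- as.character(p)
    if (is.null(trace$witness)) {
      # weighted route: paths already live on the transformed graph
      tpath <- p
    } else {
      tpath <- p[1]
      if (length(p) > 1L) {
        for (k in 2:length(p)) {
          a <- p[k - 1L]; b <- p[k]
          w <- trace$witness[[a]][[b]]
          if (is.null(w)) {
            pc_lift_error(sprintf("no closure witness for reduced edge %s->%s", a, b))
          }
          tpath <- c(tpath, w[-1])
        }
      }
    }
    out <- .pc_expand_midpoints(tpath, trace$midpoints)
    if (!is_path(orig$dag, out)) {
      pc_lift_error(sprintf("lifted sequence (%s) is not a path of the input graph",
                            paste(out, collapse = ",")))
    }
    out
  })
  chk <- verify_cover(orig, lifted)
  if (strict && !chk$ok) {
    pc_lift_error(paste0("lifted cover violates original constraints: ",
                         paste(chk$failures, collapse = "; ")))
  }
  cover_solution(lifted, orig$dag, problem, satisfied = chk$ok)
}
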