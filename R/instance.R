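#' Construct a problem instance
#'
#' Bundles a DAG with the constraint sets of the path-cover problem family:
#' required nodes `V'`, required edges `E'`, subpath constraints (long reads /
#' transfrags), paired subpath constraints (paired-end reads), and optional
#' start/end node sets `S`/`T` for the weighted problem. All constraints are
#' validated against the DAG on construction.
#'
#' `starts`/`ends` are only meaningful for the weighted problem
#' (`solve_mw_mpc_sc()`); when supplied, `starts` must contain every source of
#' the DAG and `ends` every sink.
#'
#' @param dag a `pc_dag`.
#' @param required_nodes character vector, subset of the nodes (`V'`).
#' @param required_edges edges as a list of `c(from, to)` pairs or a
#'   two-column matrix/data.frame (`E'`).
#' @param subpaths list of node sequences, each a valid path of `dag`.
#' @param pairs list of pairs of node sequences (`list(list(p1, p2), ...)`).
#' @param starts,ends optional node sets `S`, `T` (NULL = not posed; the
#'   weighted solver then defaults them to the sources/sinks).
#' @return object of class `pc_instance`.
#' @export
instance <- function(dag, required_nodes = character(), required_edges = NULL,
                     subpaths = list(), pairs = list(),
                     starts = NULL, ends = NULL) {
  if (!inherits(dag, "pc_dag")) pc_validation_error("`dag` must be a pc_dag")
  required_nodes <- unique(as.character(required_nodes))
  bad <- setdiff(required_nodes, dag$nodes)
  if (length(bad)) {
    pc_validation_error(sprintf("required node(s) not in graph: %s",
                                paste(bad, collapse = ", ")))
  }
  re <- .pc_as_edge_df(required_edges)[, c("from", "to")]
  re <- unique(re)
  key <- paste(dag$edges$from, dag$edges$to, sep = "\r")
  missing_e <- !(paste(re$from, re$to, sep = "\r") %in% key)
  if (any(missing_e)) {
    pc_validation_error(sprintf("required edge(s) absent from graph: %s",
                                paste(re$from[missing_e], re$to[missing_e],
                                      sep = "->", collapse = ", ")))
  }
  subpaths <- lapply(subpaths, as.character)
  for (i in seq_along(subpaths)) {
    if (!is_path(dag, subpaths[[i]])) {
      pc_validation_error(sprintf("subpath constraint %d is not a path of the graph", i))
    }
  }
  pairs <- lapply(pairs, function(pr) {
    if (length(pr) != 2L) pc_validation_error("each pair must hold exactly two subpaths")
    lapply(pr, as.character)
  })
  for (i in seq_along(pairs)) {
    for (j in 1:2) {
      if (!is_path(dag, pairs[[i]][[j]])) {
        pc_validation_error(sprintf("member %d of pair constraint %d is not a path", j, i))
      }
    }
  }
  if (!is.null(starts)) {
    starts <- unique(as.character(starts))
    if (!all(starts %in% dag$nodes)) pc_validation_error("starts contains unknown nodes")
    miss <- setdiff(sources_of(dag), starts)
    if (length(miss)) {
      pc_validation_error(sprintf("starts must contain every source; missing: %s",
                                  paste(miss, collapse = ", ")))
    }
  }
  if (!is.null(ends)) {
    ends <- unique(as.character(ends))
    if (!all(ends %in% dag$nodes)) pc_validation_error("ends contains unknown nodes")
    miss <- setdiff(sinks_of(dag), ends)
    if (length(miss)) {
      pc_validation_error(sprintf("ends must contain every sink; missing: %s",
                                  paste(miss, collapse = ", ")))
    }
  }
  structure(list(dag = dag, required_nodes = required_nodes,
                 required_edges = re, subpaths = subpaths, pairs = pairs,
                 starts = starts, ends = ends),
            class = "pc_instance")
}

#' @export
print.pc_instance <- function(x, ...) {
  cat(sprintf(paste0("<pc_instance> %d nodes, %d edges | V': %d, E': %d, ",
                     "subpaths: %d, pairs: %d%s\n"),
              length(x$dag$nodes), nrow(x$dag$edges),
              length(x$required_nodes), nrow(x$required_edges),
              length(x$subpaths), length(x$pairs),
              if (!is.null(x$starts)) sprintf(", |S|=%d, |T|=%d",
                                              length(x$starts), length(x$ends)) else ""))
  invisible(x)
}

# total constraint count C = |V'| + |E'| + #subpaths + #pairs
.pc_constraint_count <- function(inst) {
  length(inst$required_nodes) + nrow(inst$required_edges) +
    length(inst$subpaths) + length(inst$pairs)
}

#' Assemble a cover solution object
#'
#' @param paths list of character node sequences.
#' @param dag the original `pc_dag` (used for weight computation).
#' @param problem one of `"mpc"`, `"mpc-sc"`, `"mw-mpc-sc"`, `"mpc-psc"`.
#' @param satisfied logical certificate (set by the solvers after independent
#'   verification).
#' @return object of class `pc_cover` with `paths`, `k`, `total_weight`,
#'   `problem`, `satisfied`.
#' @export
cover_solution <- function(paths, dag, problem, satisfied = NA) {
  paths <- lapply(paths, as.character)
  structure(list(paths = paths, k = length(paths),
                 total_weight = sum(vapply(paths, function(p) path_weight(dag, p), 0)),
                 problem = problem, satisfied = satisfied),
            class = "pc_cover")
}

#' @export
print.pc_cover <- function(x, ...) {
  cat(sprintf("<pc_cover> problem=%s, k=%d, total_weight=%g, satisfied=%s\n",
              x$problem, x$k, x$total_weight, x$satisfied))
  for (p in utils::head(x$paths, 10L)) cat("  ", paste(p, collapse = " -> "), "\n")
  if (length(x$paths) > 10L) cat(sprintf("  ... %d more paths\n", length(x$paths) - 10L))
  invisible(x)
}

#' Verify a set of paths against an instance's constraints
#'
#' Independent checker used by every solver before returning (and by the CLI
#' `verify` command). Checks that each path is a valid path of the DAG, that
#' every required node/edge is covered, every subpath constraint is contained
#' contiguously in some path, both members of every pair lie contiguously on
#' the same path, and (when `S`/`T` are posed) that every path starts in `S`
#' and ends in `T`.
#'
#' @param inst a `pc_instance`.
#' @param paths list of node sequences.
#' @return list with `ok` (logical) and `failures` (character vector of
#'   human-readable reasons, empty when `ok`).
#' @export
verify_cover <- function(inst, paths) {
  dag <- inst$dag
  fails <- character()
  paths <- lapply(paths, as.character)
  for (i in seq_along(paths)) {
    if (!is_path(dag, paths[[i]])) {
      fails <- c(fails, sprintf("path %d is not a valid path of the graph", i))
    }
  }
  covered <- unique(unlist(paths))
  miss <- setdiff(inst$required_nodes, covered)
  if (length(miss)) {
    fails <- c(fails, sprintf("required node not covered: %s",
                              paste(miss, collapse = ", ")))
  }
  if (nrow(inst$required_edges)) {
    pkeys <- lapply(paths, function(p) {
      if (length(p) < 2L) character() else paste(p[-length(p)], p[-1], sep = "\r")
    })
    allk <- unique(unlist(pkeys))
    want <- paste(inst$required_edges$from, inst$required_edges$to, sep = "\r")
    bad <- which(!(want %in% allk))
    for (b in bad) {
      fails <- c(fails, sprintf("required edge not covered: %s->%s",
                                inst$required_edges$from[b], inst$required_edges$to[b]))
    }
  }
  for (i in seq_along(inst$subpaths)) {
    sp <- inst$subpaths[[i]]
    if (!any(vapply(paths, .pc_is_contiguous, TRUE, needle = sp))) {
      fails <- c(fails, sprintf("subpath constraint %d (%s) not contained in any path",
                                i, paste(sp, collapse = ",")))
    }
  }
  for (i in seq_along(inst$pairs)) {
    pr <- inst$pairs[[i]]
    ok <- any(vapply(paths, function(p) {
      .pc_is_contiguous(p, pr[[1]]) && .pc_is_contiguous(p, pr[[2]])
    }, TRUE))
    if (!ok) {
      fails <- c(fails, sprintf("pair constraint %d not satisfied by a single path", i))
    }
  }
  if (!is.null(inst$starts)) {
    for (i in seq_along(paths)) {
      p <- paths[[i]]
      if (!(p[1] %in% inst$starts)) {
        fails <- c(fails, sprintf("path %d does not start in S", i))
      }
      if (!(p[length(p)] %in% inst$ends)) {
        fails <- c(fails, sprintf("path %d does not end in T", i))
      }
    }
  }
  list(ok = length(fails) == 0L, failures = fails)
}

# ---- JSON instance / solution I/O ------------------------------------------

#' Read a problem instance from JSON
#'
#' The instance dialect is a JSON object with keys `nodes` (list), `edges`
#' (list of `[u, v]` or `[u, v, w]`), `required_nodes`, `required_edges`,
#' `subpaths` (list of node lists), `pairs` (list of two node lists),
#' `starts`, `ends`. Missing keys default to empty constraint sets; coverage
#' of all nodes is never implied, `required_nodes` is explicit.
#'
#' @param path file path or connection holding the JSON document.
#' @return a validated `pc_instance`.
#' @export
read_instance <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) pc_format_error(
                    sprintf("cannot parse instance JSON: %s", conditionMessage(e))))
  if (!is.list(doc) || is.null(doc$nodes)) {
    pc_format_error("instance JSON must be an object with at least a `nodes` key")
  }
  known <- c("nodes", "edges", "weights", "required_nodes", "required_edges",
             "subpaths", "pairs", "starts", "ends")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    pc_format_error(sprintf("unknown instance key(s): %s", paste(unknown, collapse = ", ")))
  }
  as_chr <- function(x) vapply(x, function(e) as.character(e)[1], "")
  g <- dag(as_chr(doc$nodes), doc$edges)
  instance(
    g,
    required_nodes = if (is.null(doc$required_nodes)) character() else as_chr(doc$required_nodes),
    required_edges = doc$required_edges,
    subpaths = lapply(doc$subpaths, as_chr),
    pairs = lapply(doc$pairs, function(pr) lapply(pr, as_chr)),
    starts = if (is.null(doc$starts)) NULL else as_chr(doc$starts),
    ends = if (is.null(doc$ends)) NULL else as_chr(doc$ends)
  )
}

#' Write an instance to JSON (canonical form)
#'
#' `read_instance(write_instance(x))` is stable: writing a re-read file
#' produces the identical document.
#'
#' @param inst a `pc_instance`.
#' @param path file path or connection.
#' @export
write_instance <- function(inst, path) {
  ed <- inst$dag$edges
  doc <- list(
    nodes = as.list(inst$dag$nodes),
    edges = lapply(seq_len(nrow(ed)), function(i) {
      if (ed$weight[i] != 0) list(ed$from[i], ed$to[i], ed$weight[i])
      else list(ed$from[i], ed$to[i])
    }),
    required_nodes = as.list(inst$required_nodes),
    required_edges = lapply(seq_len(nrow(inst$required_edges)), function(i) {
      list(inst$required_edges$from[i], inst$required_edges$to[i])
    }),
    subpaths = lapply(inst$subpaths, as.list),
    pairs = lapply(inst$pairs, function(pr) lapply(pr, as.list))
  )
  if (!is.null(inst$starts)) doc$starts <- as.list(inst$starts)
  if (!is.null(inst$ends)) doc$ends <- as.list(inst$ends)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cover solution to JSON
#'
#' @param sol a `pc_cover`.
#' @param path file path or connection.
#' @export
write_solution <- function(sol, path) {
  doc <- list(problem = sol$problem, num_paths = sol$k,
              paths = lapply(sol$paths, as.list),
              total_weight = sol$total_weight,
              satisfied = isTRUE(sol$satisfied))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a solution file written by [write_solution()]
#' @param path file path or connection.
#' @return list with `problem`, `num_paths`, `paths`, `total_weight`, `satisfied`.
#' @export
read_solution <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) pc_format_error(
                    sprintf("cannot parse solution JSON: %s", conditionMessage(e))))
  if (is.null(doc$paths)) pc_format_error("solution JSON lacks `paths`")
  doc$paths <- lapply(doc$paths, function(p) vapply(p, as.character, ""))
  doc
}

#' Export a DAG (optionally with solution paths) to Graphviz DOT
#'
#' @param dag a `pc_dag`.
#' @param paths optional list of node sequences; edges on path i are colored.
#' @param path output file path.
#' @export
write_dot <- function(dag, path, paths = NULL) {
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph G {")
  lines <- c(lines, paste0("  ", q(dag$nodes), ";"))
  cols <- c("red", "blue", "forestgreen", "orange", "purple", "brown")
  onpath <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (length(p) >= 2L) {
      k <- paste(p[-length(p)], p[-1], sep = "\r")
      for (kk in k) onpath[[kk]] <- cols[(i - 1L) %% length(cols) + 1L]
    }
  }
  for (i in seq_len(nrow(dag$edges))) {
    key <- paste(dag$edges$from[i], dag$edges$to[i], sep = "\r")
    attr <- if (!is.null(onpath[[key]])) {
      sprintf(" [color=%s,penwidth=2]", onpath[[key]])
    } else ""
    lines <- c(lines, sprintf("  %s -> %s%s;", q(dag$edges$from[i]),
                              q(dag$edges$to[i]), attr))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
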