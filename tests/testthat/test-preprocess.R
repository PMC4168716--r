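test_that("constraint normalization drops dominated node/edge constraints", {
  ch <- chain_dag(2)
  # V' endpoints of a required edge are dropped
  i1 <- instance(ch, required_nodes = c("1", "2"),
                 required_edges = list(c("1", "2")))
  n1 <- normalize_constraints(i1)
  expect_equal(n1$required_nodes, character())
  expect_equal(nrow(n1$required_edges), 1L)

  # nodes/edges on a subpath are dropped from V'/E'
  d <- diamond_dag()
  i2 <- instance(d, required_nodes = d$nodes,
                 required_edges = list(c("1", "2")),
                 subpaths = list(c("1", "2", "4")))
  n2 <- normalize_constraints(i2)
  expect_equal(n2$required_nodes, "3")
  expect_equal(nrow(n2$required_edges), 0L)

  # single-node subpaths become node constraints
  i3 <- instance(d, subpaths = list("3"))
  n3 <- normalize_constraints(i3)
  expect_equal(length(n3$subpaths), 0L)
  expect_equal(n3$required_nodes, "3")
})

test_that("containment removal keeps only maximal, deduplicated subpaths", {
  expect_equal(remove_contained_subpaths(list(c("1", "2", "3"), c("2", "3"))),
               list(c("1", "2", "3")))
  expect_equal(remove_contained_subpaths(list(c("1", "2"), c("1", "2"))),
               list(c("1", "2")))
  un <- list(c("1", "2", "3"), c("3", "4", "5"))
  expect_equal(remove_contained_subpaths(un), un)
})

test_that("suffix-prefix overlap length is computed by direct comparison", {
  expect_equal(longest_suffix_prefix_overlap(c("a", "b", "c"), c("b", "c", "d")), 2L)
  expect_equal(longest_suffix_prefix_overlap(c("a", "b"), c("c", "d")), 0L)
  expect_equal(longest_suffix_prefix_overlap(c("1", "2", "3"), c("3", "4", "5")), 1L)
})

test_that("iterative merging follows the longest-first rule with fixed tie-break", {
  ch <- chain_dag(5)
  fam <- list(c("1", "2", "3"), c("2", "3", "4"), c("3", "4", "5"))
  res <- merge_subpaths_iteratively(fam, dag = ch)
  expect_equal(res$subpaths, list(as.character(1:5)))
  # hand-traced merge order: (1,2,3)+(2,3,4) at len 2, then +(3,4,5) at len 2
  expect_equal(vapply(res$merges, `[[`, 0L, "len"), c(2L, 2L))
  expect_equal(res$merges[[1]]$merged, as.character(1:4))

  # disjoint families are untouched
  g <- dag(letters[1:6], list(c("a", "b"), c("b", "c"), c("d", "e"), c("e", "f")))
  fam2 <- list(c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(merge_subpaths_iteratively(fam2, dag = g)$subpaths, fam2)

  # single merge
  res3 <- merge_subpaths_iteratively(list(c("1", "2"), c("2", "3")), dag = chain_dag(3))
  expect_equal(res3$subpaths, list(c("1", "2", "3")))
})

test_that("merging is idempotent and leaves no overlaps or containments", {
  set.seed(23)
  for (rep in 1:30) {
    inst <- random_sc_instance(n = 7, max_subpaths = 4)
    sp <- remove_contained_subpaths(inst$subpaths)
    res <- merge_subpaths_iteratively(sp, dag = inst$dag)
    out <- res$subpaths
    if (length(out) >= 2L) {
      for (i in seq_along(out)) for (j in seq_along(out)) {
        if (i != j) {
          expect_equal(longest_suffix_prefix_overlap(out[[i]], out[[j]]), 0L)
        }
      }
    }
    again <- merge_subpaths_iteratively(out, dag = inst$dag)
    expect_equal(again$subpaths, out)
    expect_equal(length(again$merges), 0L)
  }
})

test_that("shortcut edges and subdivision model subpaths as required midpoints", {
  d <- diamond_dag()
  s5 <- subpaths_to_edge_constraints(d, list(c("1", "2", "4")))
  expect_equal(nrow(s5$graph), 5L)
  expect_equal(s5$econ_add, "c1")
  expect_equal(s5$shortcut$c1, c("1", "2", "4"))

  s6 <- subdivide_edge_constraints(s5$graph, s5$econ_add, nodes = d$nodes,
                                   shortcut = s5$shortcut, orig_dag = d)
  expect_equal(length(s6$vprime_add), 1L)
  mid <- s6$vprime_add
  ek <- paste(s6$dag$edges$from, s6$dag$edges$to)
  expect_true(all(c(paste("1", mid), paste(mid, "4")) %in% ek))
  expect_false("1 4" %in% ek)  # the shortcut itself is gone
  # two subpaths with the same endpoints -> two distinct midpoints, simple graph
  s5b <- subpaths_to_edge_constraints(d, list(c("1", "2", "4"), c("1", "3", "4")))
  s6b <- subdivide_edge_constraints(s5b$graph, s5b$econ_add, nodes = d$nodes,
                                    shortcut = s5b$shortcut, orig_dag = d)
  expect_equal(length(s6b$vprime_add), 2L)
  expect_false(anyDuplicated(paste(s6b$dag$edges$from, s6b$dag$edges$to)) > 0)
  # empty constraint set -> identity
  s5c <- subpaths_to_edge_constraints(d, list())
  expect_equal(nrow(s5c$graph), 4L)
})

test_that("the full reduction produces the expected classical MPC instance", {
  d <- diamond_dag()
  inst <- instance(d, required_nodes = d$nodes, subpaths = list(c("1", "2", "4")))
  red <- reduce_to_classic_mpc(inst)
  # hand-run: only node 3 and the subpath midpoint remain, incomparable
  expect_setequal(red$reduced$nodes, c("3", red$trace$midpoints[[1]]$node))
  expect_equal(nrow(red$reduced$edges), 0L)

  ch <- chain_dag(3)
  i2 <- instance(ch, required_nodes = c("1", "3"))
  r2 <- reduce_to_classic_mpc(i2)
  expect_setequal(r2$reduced$nodes, c("1", "3"))
  expect_equal(paste(r2$reduced$edges$from, r2$reduced$edges$to), "1 3")

  i3 <- instance(ch)  # nothing required
  r3 <- reduce_to_classic_mpc(i3)
  expect_equal(length(r3$reduced$nodes), 0L)
})

test_that("lifting expands witnesses and midpoints and re-verifies", {
  d <- diamond_dag()
  inst <- instance(d, required_nodes = d$nodes, subpaths = list(c("1", "2", "4")))
  red <- reduce_to_classic_mpc(inst)
  mid <- red$trace$midpoints[[1]]$node
  sol <- lift_solution(list(mid, "3"), red$trace)
  expect_equal(sol$k, 2L)
  expect_true(sol$satisfied)
  expect_true(any(vapply(sol$paths, identical, TRUE, y = c("1", "2", "4"))))

  ch <- chain_dag(3)
  r2 <- reduce_to_classic_mpc(instance(ch, required_nodes = c("1", "3")))
  s2 <- lift_solution(list(c("1", "3")), r2$trace)
  expect_equal(s2$paths, list(c("1", "2", "3")))

  # empty cover lifts to an empty, valid cover when nothing is constrained
  r3 <- reduce_to_classic_mpc(instance(ch))
  s3 <- lift_solution(list(), r3$trace)
  expect_equal(s3$k, 0L)
  expect_true(s3$satisfied)
})

test_that("optimum is preserved by normalization and merging (small random sweep)", {
  set.seed(31)
  done <- 0
  for (attempt in 1:200) {
    if (done >= 40) break
    inst <- random_sc_instance(n = sample(5:8, 1), max_subpaths = 4)
    oracle <- brute_min_cover(inst, k_max = 8L)
    if (is.null(oracle)) next
    sol <- solve_mpc_sc(inst)
    expect_equal(sol$k, oracle$k)
    expect_true(sol$satisfied)
    done <- done + 1
  }
  expect_gte(done, 40)
})
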