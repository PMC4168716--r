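test_that("joint containment merges shared nodes and orders disjoint segments", {
  d <- diamond_dag()
  r1 <- single_path_contains_all(d, list(c("1", "2"), c("2", "4")))
  expect_true(r1$ok)
  expect_equal(r1$witness, c("1", "2", "4"))
  # no maximal path of the diamond holds both branches (checked exhaustively)
  holds_both <- vapply(brute_maximal_paths(d), function(p) {
    contiguous_in(p, c("1", "2")) && contiguous_in(p, c("3", "4"))
  }, TRUE)
  expect_false(any(holds_both))
  expect_false(single_path_contains_all(d, list(c("1", "2"), c("3", "4")))$ok)

  ch <- chain_dag(5)
  r3 <- single_path_contains_all(ch, list(c("1", "2"), c("4", "5")))
  expect_true(r3$ok)
  expect_equal(r3$witness, as.character(1:5))
  expect_true(single_path_contains_all(ch, list())$ok)
})

test_that("atom compatibility reduces to joint single-path containment", {
  d <- diamond_dag()
  atom <- function(...) list(subpaths = list(...))
  expect_false(atoms_compatible(atom("2"), atom("3"), d))
  expect_true(atoms_compatible(atom("1"), atom("4"), d))
  # a pair forcing (1,2) and (2,4) pins the path to (1,2,4), which misses 3
  expect_false(atoms_compatible(atom(c("1", "2"), c("2", "4")), atom("3"), d))
})

test_that("feasibility rejects pairs no single path can host", {
  d <- diamond_dag()
  expect_error(check_feasibility(instance(d, pairs = list(list("2", "3")))),
               class = "pc_infeasible_error")
  expect_silent(check_feasibility(instance(d, pairs = list(list(c("1", "2"), c("2", "4"))))))
  expect_silent(check_feasibility(instance(d)))
})

test_that("the incompatibility graph has an edge exactly per incompatible pair", {
  d <- diamond_dag()
  ig <- build_incompatibility_graph(instance(d, required_nodes = c("2", "3")))
  expect_equal(sum(ig$adj) / 2, 1)
  ch <- chain_dag(6)
  ig2 <- build_incompatibility_graph(
    instance(ch, required_nodes = c("1", "4"),
             subpaths = list(c("2", "3")),
             pairs = list(list("1", c("5", "6")))))
  expect_false(any(ig2$adj))  # everything on a chain is orderable
  ig3 <- build_incompatibility_graph(instance(d))
  expect_equal(length(ig3$atoms), 0L)
})

test_that("the two-path decision matches bipartiteness of the incompatibility graph", {
  d <- diamond_dag()
  s1 <- solve_opt2(instance(d, required_nodes = c("2", "3")))
  expect_equal(s1$k, 2L)
  expect_true(s1$satisfied)
  s2 <- solve_opt2(instance(d, required_nodes = c("1", "4")))
  expect_equal(s2$k, 1L)
  # odd-cycle incompatibilities push the optimum past 2
  gd <- hardness_gadget(named_source_graph("k3")$vertices,
                        named_source_graph("k3")$edges)
  expect_null(solve_opt2(gd$instance))
})

test_that("class realization returns a containing path or raises", {
  d <- diamond_dag()
  atoms <- list(list(subpaths = list("1"), label = "node 1"),
                list(subpaths = list(c("2", "4")), label = "edge 2->4"))
  expect_equal(realize_class(d, atoms), c("1", "2", "4"))
  ch <- chain_dag(5)
  atoms2 <- list(list(subpaths = list(c("1", "2"), c("4", "5")), label = "pair"),
                 list(subpaths = list("3"), label = "node 3"))
  expect_equal(realize_class(ch, atoms2), as.character(1:5))
  bad <- list(list(subpaths = list("2"), label = "node 2"),
              list(subpaths = list("3"), label = "node 3"))
  expect_error(realize_class(d, bad), class = "pc_realization_error")
})

test_that("the exact solver returns the chromatic number of the incompatibility graph", {
  gd <- hardness_gadget(named_source_graph("k3")$vertices,
                        named_source_graph("k3")$edges)
  sol <- solve_mpc_psc(gd$instance, fpt_budget = 30)
  expect_equal(sol$k, 3L)
  expect_true(sol$satisfied)
  d <- diamond_dag()
  expect_equal(solve_mpc_psc(instance(d, required_nodes = "2"))$k, 1L)
  expect_equal(solve_mpc_psc(instance(d))$k, 0L)
  expect_error(solve_mpc_psc(gd$instance, fpt_budget = 5),
               class = "pc_limit_error")
})

test_that("exact coloring agrees with exhaustive assignment search", {
  set.seed(53)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    adj <- matrix(FALSE, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (runif(1) < 0.4) adj[a, b] <- adj[b, a] <- TRUE
    }
    res <- chromatic_number(adj)
    expect_equal(res$k, brute_chromatic(adj))
    # returned coloring is proper and uses k colors
    expect_equal(max(res$coloring), res$k)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (adj[a, b]) expect_true(res$coloring[a] != res$coloring[b])
    }
  }
})

test_that("solver cardinality matches the exhaustive cover oracle on paired instances", {
  set.seed(59)
  done <- 0
  for (attempt in 1:150) {
    if (done >= 40) break
    d <- random_test_dag(sample(4:7, 1), runif(1, 0.3, 0.6))
    mp <- brute_maximal_paths(d)
    if (!length(mp)) next
    natoms <- sample(1:4, 1)
    req <- character(); pairs <- list()
    for (a in seq_len(natoms)) {
      if (runif(1) < 0.5) {
        req <- union(req, sample(d$nodes, 1))
      } else {
        p <- mp[[sample.int(length(mp), 1)]]
        if (length(p) < 2) next
        i1 <- sort(sample.int(length(p), 2))
        pairs[[length(pairs) + 1]] <- list(p[i1[1]], p[i1[2]])
      }
    }
    inst <- instance(d, required_nodes = req, pairs = pairs)
    sol <- solve_mpc_psc(inst)
    oracle <- brute_min_cover(inst, k_max = 6L)
    expect_equal(sol$k, oracle$k)
    expect_true(sol$satisfied)
    done <- done + 1
  }
  expect_gte(done, 40)
})
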