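test_that("min-flow network construction splits nodes and attaches s/t", {
  d <- diamond_dag()
  net <- build_minflow_network(d)
  a <- net$arcs
  expect_equal(sum(a$kind == "node" & a$lower == 1L), 4L)
  expect_equal(sum(a$kind == "edge"), 4L)
  expect_equal(sum(a$kind == "source"), 1L)  # only node 1 is a source
  expect_equal(sum(a$kind == "sink"), 1L)
  # only required nodes carry a lower bound
  net2 <- build_minflow_network(chain_dag(3), required = "2")
  expect_equal(sum(net2$arcs$lower), 1L)
  expect_equal(net2$arcs$ref[net2$arcs$lower == 1L], "2")
  # empty graph: just s and t
  net0 <- build_minflow_network(dag(character()))
  expect_equal(nrow(net0$arcs), 0L)
  expect_equal(min_flow(net0)$value, 0)
})

test_that("min-flow value equals the maximum antichain size", {
  expect_equal(min_flow(build_minflow_network(diamond_dag()))$value, 2)
  expect_equal(min_flow(build_minflow_network(chain_dag(4)))$value, 1)
  expect_equal(min_flow(build_minflow_network(diamond_dag(), required = "2"))$value, 1)
  # exhaustive check on all DAGs with <= 4 nodes against subset enumeration
  for (g in enumerate_dags(4)) {
    expect_equal(min_flow(build_minflow_network(g))$value, brute_antichain_size(g))
  }
})

test_that("min-cost network carries weights, midpoint costs and the big circulation cost", {
  chw <- dag(1:3, list(c("1", "2", 5), c("2", "3", 7)))
  net <- build_mincost_network(chw)
  expect_equal(net$arcs$cost[net$circ], 13)  # 5 + 7 + 1
  # all-zero weights still get a strictly positive circulation cost
  net0 <- build_mincost_network(chain_dag(3))
  expect_equal(net0$arcs$cost[net0$circ], 1)
  # midpoint costs are added to split arcs
  netm <- build_mincost_network(chain_dag(3), node_cost = c("2" = 4))
  split2 <- netm$arcs$kind == "node" & netm$arcs$ref == "2"
  expect_equal(netm$arcs$cost[split2], 4)
  expect_equal(netm$arcs$cost[netm$circ], 5)
})

test_that("min-cost circulation finds the cheapest minimum flow", {
  chw <- dag(1:3, list(c("1", "2", 5), c("2", "3", 7)))
  fl <- min_cost_circulation(build_mincost_network(chw))
  expect_equal(fl$value, 1)
  expect_equal(fl$cost, 12 + 13)  # path cost plus one circulation-arc traversal
  dw <- diamond_dag(weights = c(1, 10, 1, 10))
  fl2 <- min_cost_circulation(build_mincost_network(dw, starts = "1", ends = "4"))
  expect_equal(fl2$value, 2)
  expect_equal(fl2$cost - 2 * (22 + 1), 22)
  fl3 <- min_cost_circulation(build_mincost_network(dw, starts = c("1", "3"), ends = "4"))
  expect_equal(fl3$value, 2)
  expect_equal(fl3$cost - 2 * (22 + 1), 12)
  # a required node with no route from the source set is infeasible
  bad <- build_mincost_network(diamond_dag(), required = diamond_dag()$nodes,
                               starts = "2", ends = "4")
  expect_error(min_cost_circulation(bad), class = "pc_infeasible_error")
})

test_that("flow decomposition reproduces the flow and covers required nodes", {
  d <- diamond_dag()
  net <- build_minflow_network(d)
  fl <- min_flow(net)
  dec <- decompose_flow_to_paths(fl)
  expect_equal(length(dec$paths), fl$value)
  expect_setequal(unique(unlist(dec$paths)), d$nodes)
  # arc-use counts equal the flow exactly
  use <- numeric(nrow(net$arcs))
  for (ap in dec$arc_paths) for (a in ap) use[a] <- use[a] + 1
  expect_equal(use, fl$flow)
  # zero flow decomposes into nothing
  net2 <- build_minflow_network(d, required = character())
  fl2 <- min_flow(net2)
  expect_equal(fl2$value, 0)
  expect_equal(length(decompose_flow_to_paths(fl2)$paths), 0L)
  # chain flow of value 1 gives back the chain
  ch <- chain_dag(3)
  dec3 <- decompose_flow_to_paths(min_flow(build_minflow_network(ch)))
  expect_equal(dec3$paths, list(c("1", "2", "3")))
})

test_that("decomposition conserves flow on random instances", {
  set.seed(13)
  for (i in 1:30) {
    g <- random_test_dag(sample(3:9, 1), runif(1, 0.15, 0.5))
    req <- sample(g$nodes, sample.int(length(g$nodes), 1))
    net <- build_minflow_network(g, required = req)
    fl <- min_flow(net)
    dec <- decompose_flow_to_paths(fl)
    use <- numeric(nrow(net$arcs))
    for (ap in dec$arc_paths) for (a in ap) use[a] <- use[a] + 1
    expect_equal(use, fl$flow)
    expect_true(all(req %in% unlist(dec$paths)))
  }
})

test_that("minimum-cardinality weighted covers never beat the exhaustive optimum", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    g0 <- random_test_dag(n, runif(1, 0.25, 0.5))
    g <- dag(g0$nodes, g0$edges[, c("from", "to")],
             weights = sample(0:5, nrow(g0$edges), replace = TRUE))
    sol <- solve_mpc(g, weighted = TRUE)
    oracle <- brute_min_cover(instance(g, required_nodes = g$nodes))
    expect_equal(sol$k, oracle$k)
    expect_equal(sol$total_weight, oracle$weight)
  }
})
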