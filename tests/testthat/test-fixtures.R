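test_that("the splicing-graph generator meets its postconditions", {
  p <- simulation_params(num_exons = 12, num_transcripts = 3, seed = 9)
  sim <- random_splicing_dag(p)
  expect_equal(length(sim$dag$nodes), 12L)
  # every transcript is a valid path; every node lies on one
  for (tx in sim$transcripts) expect_true(is_path(sim$dag, tx))
  expect_setequal(unique(unlist(sim$transcripts)), sim$dag$nodes)
  # one transcript makes a chain
  p1 <- simulation_params(num_exons = 6, num_transcripts = 1, seed = 2)
  s1 <- random_splicing_dag(p1)
  expect_equal(length(s1$transcripts), 1L)
  expect_equal(nrow(s1$dag$edges), length(s1$transcripts[[1]]) - 1L)
  # determinism under the seed
  again <- random_splicing_dag(p)
  expect_identical(sim, again)
})

test_that("sampled long reads and pairs are valid and satisfiable by their transcript", {
  p <- simulation_params(num_exons = 15, num_transcripts = 3,
                         num_long_reads = 8, num_pairs = 6, seed = 4)
  sim <- random_splicing_dag(p)
  reads <- sample_long_reads(sim, p)
  expect_equal(length(reads), 8L)
  for (r in reads) {
    expect_true(is_path(sim$dag, r))
    expect_true(any(vapply(sim$transcripts, function(tx) contiguous_in(tx, r), TRUE)))
  }
  prs <- sample_paired_reads(sim, p)
  expect_equal(length(prs), 6L)
  inst <- instance(sim$dag, pairs = prs)
  expect_silent(check_feasibility(inst))
  # a mate pair sits in order on one transcript
  for (pr in prs) {
    on_same <- vapply(sim$transcripts, function(tx) {
      contiguous_in(tx, pr[[1]]) && contiguous_in(tx, pr[[2]])
    }, TRUE)
    expect_true(any(on_same))
  }
  # empty samplers
  p0 <- simulation_params(num_long_reads = 0, num_pairs = 0)
  expect_equal(length(sample_long_reads(sim, p0)), 0L)
  expect_equal(length(sample_paired_reads(sim, p0)), 0L)
  # a read at least as long as its transcript is the whole transcript
  pl <- simulation_params(num_exons = 6, num_transcripts = 1,
                          read_length = 99, num_long_reads = 2, seed = 3)
  sl <- random_splicing_dag(pl)
  for (r in sample_long_reads(sl, pl)) expect_equal(r, sl$transcripts[[1]])
})

test_that("generated constraints are consistent with the ground-truth cover", {
  set.seed(77)
  for (s in 1:5) {
    p <- simulation_params(num_exons = 12, num_transcripts = 3,
                           num_long_reads = 6, seed = s)
    sim <- random_splicing_dag(p)
    inst <- instance(sim$dag, required_nodes = sim$dag$nodes,
                     subpaths = sample_long_reads(sim, p))
    expect_true(verify_cover(inst, sim$transcripts)$ok)
    sol <- solve_mpc_sc(inst)
    expect_lte(sol$k, p$num_transcripts)
    expect_true(sol$satisfied)
  }
})

test_that("the hardness gadget has the advertised structure", {
  src <- named_source_graph("k3")
  gd <- hardness_gadget(src$vertices, src$edges)
  inst <- gd$instance
  # only paired constraints
  expect_equal(length(inst$required_nodes), 0L)
  expect_equal(nrow(inst$required_edges), 0L)
  expect_equal(length(inst$subpaths), 0L)
  expect_equal(length(inst$pairs), 2 * 3 + 3 * 3)  # 2m + 3n
  # every labeled branch appears in some constraint
  used <- unique(unlist(inst$pairs, recursive = FALSE))
  for (lab in names(gd$labels)) {
    expect_true(any(vapply(used, identical, TRUE, y = gd$labels[[lab]])),
                info = lab)
  }
  expect_silent(check_feasibility(inst))
  # bad source graphs are rejected
  expect_error(hardness_gadget(c("a", "b"), list(c("a", "b"))),
               class = "pc_gadget_error")
  expect_error(hardness_gadget(c("a", "b", "c", "z"),
                               list(c("a", "b"), c("b", "c"), c("a", "c"))),
               class = "pc_gadget_error")
})

test_that("gadget optimum equals 3 exactly when the source graph is 3-chromatic", {
  # non-bipartite graphs on <= 5 vertices with chromatic number 3 and 4
  cases <- list(
    list(g = named_source_graph("k3"), chi = 3L),
    list(g = named_source_graph("c5"), chi = 3L),
    list(g = named_source_graph("k4"), chi = 4L),
    # triangle plus pendant edge: still 3-chromatic
    list(g = list(vertices = c("a", "b", "c", "d"),
                  edges = list(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d"))),
         chi = 3L)
  )
  for (cs in cases) {
    # independent chromatic number of the source graph
    n <- length(cs$g$vertices)
    adj <- matrix(FALSE, n, n, dimnames = list(cs$g$vertices, cs$g$vertices))
    for (e in cs$g$edges) adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
    expect_equal(brute_chromatic(adj), cs$chi)
    gd <- hardness_gadget(cs$g$vertices, cs$g$edges)
    sol <- solve_mpc_psc(gd$instance, fpt_budget = 40)
    expect_equal(sol$k, cs$chi)
    expect_equal(sol$k == 3L, cs$chi == 3L)
  }
})

test_that("overlap-chain fixtures are valid and separate the two pipelines", {
  inst <- overlap_chain_fixture(3)
  expect_equal(length(inst$subpaths), 3L)
  for (p in inst$subpaths) expect_true(is_path(inst$dag, p))
  expect_error(overlap_chain_fixture(1), class = "pc_validation_error")
  full <- solve_mpc_sc(inst)
  expect_equal(full$k, 1L)
  naive <- solve_mpc_sc(inst, naive = TRUE)
  expect_gt(naive$k, full$k)
})
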