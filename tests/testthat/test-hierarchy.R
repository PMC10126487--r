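edge_df <- function(from, to) data.frame(from = from, to = to,
                                         stringsAsFactors = FALSE)

test_that("condensation handles DAGs, cycles and joined cycles", {
  dag <- edge_df(c("a", "a", "b"), c("b", "c", "c"))
  cond <- condense(dag)
  expect_true(all(cond$alpha == 1))
  expect_equal(igraph::ecount(cond$dag), 3)
  expect_false(any(cond$cyclic))

  cyc <- edge_df(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  cond2 <- condense(cyc)
  expect_equal(unname(cond2$alpha), 4L)
  expect_equal(igraph::vcount(cond2$dag), 1)

  two <- edge_df(c("a", "b", "c", "x", "y", "z", "c"),
                 c("b", "c", "a", "y", "z", "x", "x"))
  cond3 <- condense(two)
  expect_equal(sort(unname(cond3$alpha)), c(3L, 3L))
  expect_equal(igraph::ecount(cond3$dag), 1)

  # self-loops: cyclic singleton, but no condensation edge
  selfy <- edge_df(c("a", "a"), c("a", "b"))
  cond4 <- condense(selfy)
  expect_true(cond4$cyclic[cond4$membership["a"]])
  expect_false(cond4$cyclic[cond4$membership["b"]])
  expect_error(condense(edge_df(character(), character())), "empty")
})

test_that("SCC membership agrees with brute-force mutual reachability", {
  withr::with_seed(23, {
    for (k in 1:25) {
      g <- random_digraph(sample(2:6, 1), stats::runif(1, 0.1, 0.6),
                          seed = sample(1e6, 1))
      cond <- condense(as_dependency_graph(g$edges, nodes = g$nodes))
      ours <- cond$membership[g$nodes]
      brute <- oracle_scc(g$edges, g$nodes)
      # same partition: equal membership up to label permutation
      expect_equal(outer(ours, ours, "=="), outer(brute, brute, "=="),
                   ignore_attr = TRUE)
    }
  })
})

test_that("orderability worked examples", {
  cyc5 <- edge_df(c("a", "b", "c", "d", "e"), c("b", "c", "d", "e", "a"))
  expect_equal(orderability(cyc5), 0)
  dag <- edge_df(c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(orderability(dag), 1)
  # 5-cycle plus 5 pendant nodes: half the nodes sit outside the loop
  pend <- edge_df(c("a", "b", "c", "d", "e", "a", "b", "c", "d", "e"),
                  c("b", "c", "d", "e", "a", "p1", "p2", "p3", "p4", "p5"))
  expect_equal(orderability(pend), 0.5)
  # a self-loop keeps its node inside a loop
  expect_equal(orderability(edge_df(c("a", "a"), c("a", "b"))), 0.5)
})

test_that("path entropies match closed forms and path enumeration", {
  star <- edge_df(rep("h", 8), paste0("l", 1:8))
  h <- path_entropies(condense(star))
  expect_equal(unname(h["H_f"]), log2(8))
  expect_equal(unname(h["H_b"]), 0)

  chain <- edge_df(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(unname(path_entropies(condense(chain))), c(0, 0))

  # complete binary out-tree of depth 2: one bit per level
  tree <- edge_df(c("r", "r", "u", "u", "v", "v"),
                  c("u", "v", "a", "b", "c", "d"))
  expect_equal(unname(path_entropies(condense(tree))["H_f"]), 2)

  # random DAGs: recursive entropies equal explicit path-enumeration entropies
  withr::with_seed(29, {
    tried <- 0
    while (tried < 10) {
      n <- sample(3:6, 1)
      ids <- sprintf("v%d", 1:n)
      # forward-ordered edges guarantee acyclicity
      el <- expand.grid(i = 1:n, j = 1:n)
      el <- el[el$i < el$j & stats::runif(nrow(el)) < 0.5, ]
      if (nrow(el) == 0) next
      tried <- tried + 1
      df <- edge_df(ids[el$i], ids[el$j])
      cond <- condense(as_dependency_graph(df, nodes = ids))
      maximal <- ids[!ids %in% df$to]
      by_enum <- mean(vapply(maximal, function(v)
        oracle_path_entropy(df, ids, v), numeric(1)))
      expect_equal(unname(path_entropies(cond)["H_f"]), by_enum)
    }
  })
})

test_that("treeness worked examples and edge-reversal antisymmetry", {
  star <- edge_df(rep("h", 5), paste0("l", 1:5))
  expect_equal(as.numeric(treeness(star)), 1)
  expect_equal(as.numeric(treeness(star[, 2:1])), -1)
  chain <- edge_df(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(as.numeric(treeness(chain)), 0)

  withr::with_seed(37, {
    for (k in 1:25) {
      g <- random_digraph(sample(3:6, 1), stats::runif(1, 0.15, 0.5),
                          seed = sample(1e6, 1))
      if (nrow(g$edges) == 0) next
      gr <- as_dependency_graph(g$edges, nodes = g$nodes)
      t_fwd <- as.numeric(treeness(gr))
      t_rev <- as.numeric(treeness(igraph::reverse_edges(gr)))
      expect_equal(t_rev, -t_fwd)
      expect_gte(t_fwd, -1)
      expect_lte(t_fwd, 1)
    }
  })
})

test_that("feedforwardness worked examples and reversal invariance", {
  dag <- edge_df(c("a", "a", "b"), c("b", "c", "c"))
  expect_equal(feedforwardness(dag), 1)

  cyc4 <- edge_df(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  expect_equal(feedforwardness(cyc4), 1 / 4)

  # 2-cycle feeding a singleton sink: single path with sizes (2, 1)
  mix <- edge_df(c("a", "b", "a"), c("b", "a", "s"))
  expect_equal(feedforwardness(mix), 2 / 3)

  withr::with_seed(41, {
    for (k in 1:15) {
      g <- random_digraph(sample(3:6, 1), stats::runif(1, 0.15, 0.5),
                          seed = sample(1e6, 1))
      if (nrow(g$edges) == 0) next
      gr <- as_dependency_graph(g$edges, nodes = g$nodes)
      expect_equal(feedforwardness(igraph::reverse_edges(gr)),
                   feedforwardness(gr))
      expect_equal(orderability(igraph::reverse_edges(gr)), orderability(gr))
    }
  })
})

test_that("growing an SCC along a path strictly decreases its score", {
  # same condensation shape (cycle -> sink), increasing cycle size
  cyc_to_sink <- function(k) {
    ids <- paste0("c", 1:k)
    edge_df(c(ids, ids[1]), c(ids[-1], ids[1], "s"))
  }
  f3 <- feedforwardness(cyc_to_sink(3))
  f5 <- feedforwardness(cyc_to_sink(5))
  # single path of 2 condensation nodes over k + 1 original nodes: 2 / (k + 1)
  expect_equal(f3, 2 / 4)
  expect_equal(f5, 2 / 6)
  expect_lt(f5, f3)
  # the same graphs via hierarchy_report expose the path-level effect
  expect_lt(orderability(cyc_to_sink(5)), orderability(cyc_to_sink(3)))
})

test_that("isolated nodes are counted and a path explosion errors", {
  # isolated nodes: singleton maximal-and-minimal SCCs with trivial paths
  g <- as_dependency_graph(edge_df("a", "b"), nodes = c("a", "b", "iso"))
  expect_equal(orderability(g), 1)
  expect_equal(feedforwardness(g), 1)
  rep <- hierarchy_report(g)
  expect_equal(rep$n_nodes, 3)

  # layered complete DAG has exponentially many paths
  layers <- 10
  from <- character(0); to <- character(0)
  for (l in 1:layers) {
    for (i in 1:3) for (j in 1:3) {
      from <- c(from, sprintf("n%d_%d", l, i))
      to <- c(to, sprintf("n%d_%d", l + 1, j))
    }
  }
  expect_error(feedforwardness(edge_df(from, to), max_paths = 100),
               "max_paths")
})

test_that("hierarchy report fields are mutually consistent", {
  mod <- simulate_exchange_community(n_species = 6, loop_count = 1, seed = 3)
  net <- build_network(replicate_runs(mod, n_runs = 2), day = 1)
  rep <- hierarchy_report(net)
  expect_equal(rep$treeness, as.numeric(treeness(net)))
  expect_equal(rep$feedforwardness, feedforwardness(net))
  expect_equal(rep$orderability, orderability(net))
  expect_equal(nrow(tidy(rep)), 5)
  expect_equal(glance(rep)$n_nodes, 6)
  # feedback loop present -> orderability below one
  expect_lt(rep$orderability, 1)
})
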