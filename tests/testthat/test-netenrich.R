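test_that("interaction graphs enforce their invariants", {
  expect_error(interaction_graph(data.frame(node1 = "A", node2 = "A")),
               "self-edges")
  expect_error(interaction_graph(
    data.frame(node1 = c("A", "B"), node2 = c("B", "A"))), "duplicate")
  expect_error(interaction_graph(
    data.frame(node1 = "A", node2 = "B", score = 1.4)), "scores")
  g <- interaction_graph(data.frame(node1 = "B", node2 = "A"))
  expect_equal(g$edges$node1, "A")  # canonical order
})

test_that("average node degree follows 2E/N on induced subgraphs", {
  g <- toy_graph()
  expect_equal(as.numeric(average_node_degree(c("A", "B", "C"), g)), 2)
  expect_equal(as.numeric(average_node_degree(c("B", "C", "D"), g)), 2 / 3)
  expect_equal(as.numeric(average_node_degree(c("A", "F"), g)), 0)
  # unmatched genes are dropped before computing D
  d <- average_node_degree(c("A", "B", "C", "ZZZ"), g)
  expect_equal(as.numeric(d), 2)
  expect_equal(attr(d, "n_matched"), 3)
  expect_error(average_node_degree(c("X", "Y"), g), "empty module")

  # property: D equals the mean degree of the induced subgraph
  set.seed(90)
  bg <- simulate_background_graph(60, 6, seed = 12)
  for (i in 1:5) {
    genes <- sample(bg$nodes, 20)
    sub <- igraph::induced_subgraph(
      igraph::graph_from_data_frame(bg$edges[, 1:2], directed = FALSE,
                                    vertices = bg$nodes), genes)
    expect_equal(as.numeric(average_node_degree(genes, bg)),
                 mean(igraph::degree(sub)))
  }
})

test_that("degree null on a complete graph is an exact line", {
  n <- 40
  pairs <- t(utils::combn(sprintf("K%02d", 1:n), 2))
  kn <- interaction_graph(data.frame(node1 = pairs[, 1], node2 = pairs[, 2]))
  null <- monte_carlo_degree_null(kn, sizes = c(5, 10, 20, 30), reps = 200,
                                  seed = 13)
  # every size-n sample of K_N induces K_n: D = n - 1 exactly
  for (f in null$fits) {
    expect_equal(f$slope, 1, tolerance = 1e-12)
    expect_equal(f$intercept, -1, tolerance = 1e-9)
    expect_equal(f$r2, 1, tolerance = 1e-12)
  }
  expect_error(monte_carlo_degree_null(kn, sizes = 100, reps = 200),
               "exceeds")
})

test_that("degree null tracks the Erdos-Renyi closed form", {
  g <- simulate_background_graph(800, 10, seed = 14)
  null <- monte_carlo_degree_null(g, sizes = c(25, 50, 100, 200),
                                  reps = 400, seed = 15)
  # E[D | size n] = (n - 1) * p with p = 10/799
  p <- 10 / 799
  expect_equal(null$null_mean, (null$sizes - 1) * p, tolerance = 0.1)
  # quantiles are monotone non-decreasing in size
  for (i in seq_along(null$alphas)) {
    expect_true(all(diff(null$quantiles[i, ]) >= 0))
  }
  # the alpha=0.01 line sits above the alpha=0.05 line over the grid
  expect_true(all(null$quantiles["alpha_0.01", ] >=
                  null$quantiles["alpha_0.05", ]))
})

test_that("module enrichment flags planted cliques and not random sets", {
  g <- simulate_background_graph(500, 8, seed = 16)
  mod <- g$nodes[1:40]
  g2 <- embed_module_edges(g, mod, 0.6, seed = 17)
  null <- monte_carlo_degree_null(g2, sizes = c(20, 40, 60, 80), reps = 300,
                                  seed = 18)
  res <- module_enrichment(mod, g2, null, name = "planted")
  expect_true(res$enriched_0.05)
  expect_true(res$enriched_0.01)
  expect_gt(res$D, res$ED_0.01)

  iso <- interaction_graph(data.frame(node1 = "A", node2 = "B"),
                           nodes = c("A", "B", sprintf("I%02d", 1:60)))
  null_iso <- monte_carlo_degree_null(iso, sizes = c(10, 20, 30),
                                      reps = 100, seed = 19)
  res0 <- module_enrichment(sprintf("I%02d", 1:12), iso, null_iso)
  expect_equal(res0$D, 0)
  expect_false(res0$enriched_0.05)

  expect_warning(module_enrichment(g2$nodes[1:5], g2, null), "extrapolated")
})

test_that("interactome assembly respects precedence, thresholds, self-edges", {
  tabs <- data.frame(
    node1 = c("A", "A", "B", "C", "C", "D"),
    node2 = c("B", "B", "B", "D", "D", "E"),
    score = c(1.0, 0.9, 0.5, 0.65, 0.65, 0.65),
    source = c("STRING-text", "PPI", "self", "STRING-db/exp",
               "STRING-db/exp", "STRING-db/exp"),
    stringsAsFactors = FALSE
  )
  tabs$source[3] <- "PPI"; tabs$node1[3] <- "B"  # make row 3 a self-edge
  expect_error(assemble_interactome(
    data.frame(node1 = "A", node2 = "B", score = 1, source = "mystery")),
    "mystery")

  # duplicate C-D rows collapse; the same pair from PPI and STRING-text
  # keeps the PPI annotation
  tabs2 <- tabs[-5, ]
  ig <- assemble_interactome(tabs2,
                             score_threshold = c(`STRING-db/exp` = 0.7,
                                                 `STRING-text` = 0.7))
  ab <- ig$edges[ig$edges$node1 == "A" & ig$edges$node2 == "B", ]
  expect_equal(ab$source, "PPI")
  expect_false(any(ig$edges$node1 == ig$edges$node2))
  # 0.65-score database edges fall below the 0.7 threshold...
  expect_false(any(ig$edges$node1 == "C"))
  # ...but pass a 0.4 threshold
  ig4 <- assemble_interactome(tabs2,
                              score_threshold = c(`STRING-db/exp` = 0.4,
                                                  `STRING-text` = 0.4))
  expect_true(any(ig4$edges$node1 == "C" & ig4$edges$node2 == "D"))
})

test_that("fisher_overlap is the upper-tail hypergeometric probability", {
  expect_equal(fisher_overlap(0, 10, 20, 100), 1)
  # brute-force enumerable case: all C(6,3) subsets, 10 of 20 overlap >= 2
  expect_equal(fisher_overlap(2, 3, 3, 6), 0.5)
  expect_error(fisher_overlap(5, 3, 10, 100), "inconsistent")
  expect_error(fisher_overlap(2, 3, 3, 2), "inconsistent")
  # agrees with the one-sided fisher.test formulation
  ft <- stats::fisher.test(matrix(c(4, 6, 16, 74), 2), alternative = "greater")
  expect_equal(fisher_overlap(4, 10, 20, 100), ft$p.value)
})
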