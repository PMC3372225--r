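test_that("simulated cohorts have the configured design and are seeded", {
  cfg <- balanced_config(donors = 5L, seed = 11L, n_probes = 220L,
                         n_genes = 200L)
  sim <- simulate_study(cfg)
  st <- sim$study
  # 5 donors x 7 classes x 2 regions = 70 samples per tissue, 140 in all
  expect_equal(ncol(st$expr[["RPE-choroid"]]), 70)
  expect_equal(ncol(st$expr[["retina"]]), 70)
  expect_equal(nrow(st$meta), 140)
  expect_equal(nrow(st$expr[[1]]), 220)

  # per-sample linear values are on the net-intensity scale
  for (tis in names(st$expr)) {
    expect_equal(colSums(st$expr[[tis]]),
                 stats::setNames(rep(1e5, 70), colnames(st$expr[[tis]])),
                 tolerance = 1e-9)
  }

  sim2 <- simulate_study(cfg)
  expect_identical(sim$study$expr, sim2$study$expr)
  expect_identical(sim$truth, sim2$truth)

  sim3 <- simulate_study(balanced_config(donors = 5L, seed = 12L,
                                         n_probes = 220L, n_genes = 200L))
  expect_false(identical(sim$study$expr, sim3$study$expr))
})

test_that("planted module shifts appear at the configured effect size", {
  cfg <- balanced_config(
    donors = 12L, seed = 21L, n_probes = 420L, n_genes = 400L,
    planted_modules = data.frame(phenotype = "DryAMD", region = "macula",
                                 direction = "Up", n_genes = 30L,
                                 effect = 1.0, tissue = "RPE-choroid")
  )
  sim <- simulate_study(cfg)
  st <- sim$study
  meta <- sample_meta(st, "RPE-choroid")
  lg <- log2(st$expr[["RPE-choroid"]])
  probes <- st$probe_map$probe_id[st$probe_map$gene %in%
                                  sim$truth$module_membership$gene]
  dry <- meta$phenotype == "DryAMD" & meta$region == "macula"
  nrm <- meta$phenotype == "Normal" & meta$region == "macula"
  diffs <- rowMeans(lg[probes, dry]) - rowMeans(lg[probes, nrm])
  # mean planted shift within 3 SE of the configured 1.0 log2 effect
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.0), 3 * se + 0.05)

  # genes outside any planted structure stay centered on zero; compare on
  # the quantile-normalized scale, which removes the compositional bias the
  # per-sample net-intensity scaling introduces when modules shift sums
  special <- c(sim$truth$module_membership$gene,
               unlist(sim$truth$contaminants), sim$truth$gender_genes)
  null_probes <- st$probe_map$probe_id[!(st$probe_map$gene %in% special)]
  lq <- log2(quantile_normalize(st$expr[["RPE-choroid"]]))
  nd <- rowMeans(lq[null_probes, dry]) - rowMeans(lq[null_probes, nrm])
  # a residual compositional offset of a few hundredths of a log2 unit
  # survives quantile normalization (planted shifts perturb per-sample
  # totals); null genes must sit an order of magnitude below the planted
  # 1.0 log2 effect
  expect_lt(abs(mean(nd)), 0.1)
})

test_that("contaminant genes are tissue-exclusive and truth is disjoint", {
  sim <- simulate_study(small_config(seed = 31L))
  tr <- sim$truth
  st <- sim$study
  # contaminants of a tissue are the genes expressed only in the other one
  expect_identical(tr$contaminants[["RPE-choroid"]],
                   tr$expressed_only_in[["retina"]])
  expect_length(intersect(tr$module_membership$gene,
                          unlist(tr$contaminants)), 0)
  expect_length(intersect(tr$gender_genes, unlist(tr$contaminants)), 0)
  # a retina-exclusive gene sits near floor in RPE-choroid and high in retina
  g <- tr$expressed_only_in[["retina"]][1]
  pr <- st$probe_map$probe_id[st$probe_map$gene == g]
  expect_lt(mean(st$expr[["RPE-choroid"]][pr, ]), 100)
  expect_gt(mean(st$expr[["retina"]][pr, ]), 100)
})

test_that("cohort validation rejects impossible configurations", {
  expect_error(cohort_config(donors_per_class = c(Normal = 0L, GA = 5L)),
               "no reference class")
  expect_error(cohort_config(donors_per_class = c(Normal = 3L, Wet = 2L)),
               "unknown phenotype")
  expect_error(cohort_config(contaminant_fraction = 1.2), "contaminant_fraction")
  expect_error(
    cohort_config(planted_modules = data.frame(
      phenotype = "GA", region = "macula", direction = "Up",
      n_genes = 10L, effect = -1)),
    "effect")
})

test_that("background graphs are Erdos-Renyi with the requested density", {
  # edge probability 1 gives the complete graph
  k4 <- simulate_background_graph(4, 3, seed = 1)
  expect_equal(nrow(k4$edges), 6)

  g <- simulate_background_graph(1000, 10, seed = 5)
  mean_deg <- 2 * nrow(g$edges) / 1000
  # binomial SE of the mean degree
  p <- 10 / 999
  se <- sqrt(choose(1000, 2) * p * (1 - p)) * 2 / 1000
  expect_lt(abs(mean_deg - 10), 3 * se)

  g2 <- simulate_background_graph(1000, 10, seed = 5)
  expect_identical(g$edges, g2$edges)
  expect_error(simulate_background_graph(100, 0), "mean_degree")
})

test_that("embed_module_edges plants within-set density", {
  g <- simulate_background_graph(50, 4, seed = 2)
  expect_identical(embed_module_edges(g, g$nodes[1:10], 0, seed = 3), g)

  clique <- embed_module_edges(g, g$nodes[1:5], 1, seed = 3)
  d <- average_node_degree(g$nodes[1:5], clique)
  expect_equal(as.numeric(d), 4)

  empty <- interaction_graph(data.frame(node1 = character(),
                                        node2 = character()),
                             nodes = sprintf("N%03d", 1:100))
  half <- embed_module_edges(empty, empty$nodes, 0.5, seed = 4)
  expected <- 0.5 * choose(100, 2)
  se <- sqrt(choose(100, 2) * 0.25)
  expect_lt(abs(nrow(half$edges) - expected), 3 * se)

  expect_error(embed_module_edges(g, "NOPE", 0.5), "NOPE")
})
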