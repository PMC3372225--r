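test_that("comparison enumeration gives the full combinatorial design", {
  cmp <- enumerate_comparisons()
  expect_equal(nrow(cmp), 21)
  expect_equal(length(unique(cmp$comparison_id)), 21)
  # deterministic order: groups outer, scopes inner
  expect_equal(cmp$phenotype_group[1:3], rep("MD1", 3))
  expect_equal(cmp$region_scope[1:3], c("macula", "extramacula", "both"))

  expect_equal(nrow(enumerate_comparisons(groups = "GA")), 3)
  both <- enumerate_comparisons(tissues = tissue_levels())
  expect_equal(nrow(both), 42)
  expect_equal(length(unique(both$comparison_id)), 42)
})

test_that("significance scores are signed -log10 p with a cap", {
  mk <- function(p, dir, rep) {
    data.frame(probe_id = c("g1", "g2", "g3"), p_perm = p, direction = dir,
               reported = rep, stringsAsFactors = FALSE)
  }
  res <- list(
    c1 = mk(c(0.001, 0.1, 0), c("up", "up", "down"), c(TRUE, FALSE, TRUE))
  )
  S <- significance_matrix(res, n_perm = 1000)
  expect_equal(S["g1", "c1"], 3)          # -log10(0.001), up
  expect_equal(S["g2", "c1"], 0)          # not reported
  expect_equal(S["g3", "c1"], -4)         # p = 0 capped at log10(1000) + 1

  dup <- list(c1 = rbind(res$c1, res$c1[1, ]))
  expect_error(significance_matrix(dup), "duplicate")
})

test_that("probe collapsing averages rows per gene", {
  S <- matrix(c(2, 4, 5, 2, -2, 0), ncol = 2,
              dimnames = list(c("p1", "p2", "p3"), c("c1", "c2")))
  pm <- data.frame(probe_id = c("p1", "p2"), gene = c("gA", "gA"))
  out <- collapse_probes(S, pm)
  expect_equal(out["gA", ], c(c1 = 3, c2 = 0))  # mean(2,4); mean(2,-2)
  expect_equal(out["p3", ], c(c1 = 5, c2 = 0))  # unmapped kept as probe

  single <- collapse_probes(S, data.frame(probe_id = "p1", gene = "gX"))
  expect_equal(single["gX", ], S["p1", ])
})

test_that("clustering normalization has unit column sum of squares", {
  set.seed(60)
  S <- matrix(rnorm(80), 20, 4, dimnames = list(paste0("g", 1:20), NULL))
  S[5, ] <- 0
  M <- normalize_for_clustering(S)
  expect_equal(unname(colSums(M^2)), rep(1, 4))
  expect_equal(M[5, ], S[5, ])  # all-zero row untouched

  Sz <- S; Sz[, 2] <- 7
  expect_warning(normalize_for_clustering(Sz), "zero-variance")
})

test_that("consensus clustering recovers planted blocks exactly", {
  M <- block_matrix(n_per_block = 10, noise_sd = 0.1)
  # with only two planted patterns, base runs at k > 2 split the blocks
  # arbitrarily, so co-association within a block is high but not 1;
  # majority co-clustering recovers the planted partition exactly
  cc <- consensus_cluster(M, runs = 60, confidence = 0.5, seed = 3,
                          k_range = 2:3)
  memb <- cc$membership
  expect_equal(length(unique(memb[1:10])), 1)
  expect_equal(length(unique(memb[11:20])), 1)
  expect_false(memb[1] == memb[11])
  # adjusted-Rand-style check: partition matches the planted one
  expect_equal(length(unique(memb)), 2)

  # identical rows always co-associate at 1
  Md <- rbind(M, M[1, , drop = FALSE])
  rownames(Md)[21] <- "dup"
  cc2 <- consensus_cluster(Md, runs = 40, confidence = 0.99, seed = 4)
  expect_equal(cc2$coassociation["g01", "dup"], 1)
  expect_equal(cc2$membership[["g01"]], cc2$membership[["dup"]])

  # determinism
  cc3 <- consensus_cluster(M, runs = 60, confidence = 0.5, seed = 3,
                           k_range = 2:3)
  expect_identical(cc$membership, cc3$membership)

  expect_error(consensus_cluster(M[1, , drop = FALSE]), "2 rows")
})

test_that("pure-noise rows do not form large consensus clusters", {
  set.seed(70)
  N <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(sprintf("n%02d", 1:60), NULL))
  cc <- consensus_cluster(N, runs = 100, confidence = 0.995, seed = 7)
  expect_lte(max(table(cc$membership)), 3)
})

test_that("module assembly labels clusters by their dominant phenotype", {
  cmp <- enumerate_comparisons(tissues = "RPE-choroid")
  genes <- sprintf("g%02d", 1:8)
  S <- matrix(0, 8, nrow(cmp), dimnames = list(genes, cmp$comparison_id))
  glob <- cmp$comparison_id[cmp$phenotype_group == "Global"]
  ga <- cmp$comparison_id[cmp$phenotype_group == "GA"]
  S[1:4, glob] <- 3                      # Global Up cluster
  S[5:8, ga] <- -c(4, 4, 3, 3)           # GA Down cluster
  memb <- c(rep(1, 2), rep(2, 2), rep(3, 4))
  names(memb) <- genes
  mods <- assemble_modules(memb, S, cmp)
  # clusters 1 and 2 share the Global Up label and merge
  expect_setequal(mods$gene[mods$module == "RPE-choroid Global Up"],
                  genes[1:4])
  expect_setequal(mods$gene[mods$module == "RPE-choroid GA Down"],
                  genes[5:8])
  expect_equal(sort(unique(mods$module)),
               c("RPE-choroid GA Down", "RPE-choroid Global Up"))

  # a cluster with support in only one comparison column is dropped
  S2 <- S
  S2[5:8, ] <- 0
  S2[5:8, ga[1]] <- -4
  mods2 <- assemble_modules(memb, S2, cmp)
  expect_false(any(mods2$phenotype == "GA"))

  # all-zero cluster is dropped silently
  S3 <- S; S3[1:4, ] <- 0
  mods3 <- assemble_modules(memb, S3, cmp)
  expect_false(any(mods3$gene %in% genes[1:4]))
})

test_that("capped profiles significant everywhere are labeled Global", {
  cmp <- enumerate_comparisons(tissues = "RPE-choroid")
  genes <- sprintf("g%02d", 1:4)
  S <- matrix(4, 4, nrow(cmp), dimnames = list(genes, cmp$comparison_id))
  memb <- stats::setNames(rep(1, 4), genes)
  mods <- assemble_modules(memb, S, cmp)
  expect_equal(unique(mods$module), "RPE-choroid Global Up")
})
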