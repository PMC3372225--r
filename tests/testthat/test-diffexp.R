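test_that("welch_t matches the closed-form Welch evaluation", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  # independent oracle: the Welch formula written out by hand
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  r <- welch_t(a, b)
  expect_equal(r$t, t_hand)
  expect_equal(r$df, df_hand)
  expect_equal(r$p, 2 * pt(-abs(t_hand), df_hand))
  # and against the stock implementation
  tt <- t.test(a, b)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)

  # antisymmetry
  r2 <- welch_t(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate variance")
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("vectorized Welch statistics agree with t.test row by row", {
  set.seed(10)
  X <- matrix(rnorm(20 * 12), 20, 12)
  isA <- rep(c(TRUE, FALSE), each = 6)
  w <- amdmodules:::row_welch_multi(X, matrix(as.numeric(isA)))
  for (i in c(1, 7, 20)) {
    tt <- t.test(X[i, isA], X[i, !isA])
    expect_equal(w$t[i, 1], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(w$df[i, 1], unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("permuted p-values behave at the boundaries and under the null", {
  set.seed(20)
  X <- matrix(rnorm(60 * 16), 60, 16)
  labels <- rep(c("u", "v"), each = 8)
  X[1, labels == "u"] <- X[1, labels == "u"] + 50  # most extreme probe
  p <- permute_p(X, labels, n_perm = 300, seed = 2)
  expect_equal(p[1], 0)
  expect_true(all(p >= 0 & p <= 1))

  # add-one correction never returns 0
  p1 <- permute_p(X, labels, n_perm = 300, seed = 2, add_one = TRUE)
  expect_equal(p1[1], 1 / 301)

  # invariant to probe order and label renaming
  ord <- rev(seq_len(nrow(X)))
  expect_equal(permute_p(X[ord, ], labels, n_perm = 100, seed = 4),
               permute_p(X, labels, n_perm = 100, seed = 4)[ord])
  expect_equal(permute_p(X, ifelse(labels == "u", "M", "F"),
                         n_perm = 100, seed = 4),
               permute_p(X, labels, n_perm = 100, seed = 4))

  # null calibration: fraction below 0.05 close to 0.05
  set.seed(30)
  Xn <- matrix(rnorm(400 * 16), 400, 16)
  pn <- permute_p(Xn, labels, n_perm = 400, seed = 5)
  frac <- mean(pn <= 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(frac - 0.05), 3 * se + 1 / 400)

  expect_error(permute_p(Xn, rep("u", 16), 10), "two classes")
  expect_error(permute_p(Xn[, 1:3], c("u", "u", "v"), 10), ">= 2 members")

  pb <- permute_p(Xn[1:5, ], labels, n_perm = 1, seed = 6)
  expect_true(all(pb %in% c(0, 1)))
})

test_that("q-values implement the step-down minimum and estimate pi0", {
  expect_equal(as.numeric(qvalues(1)), 1)
  q <- qvalues(c(0.005, 0.01, 0.9, 0.95), pi0 = 1)
  expect_equal(as.numeric(q), c(0.02, 0.02, 0.95, 0.95))
  # with pi0 = 1 this is exactly Benjamini-Hochberg
  set.seed(40)
  p <- runif(500)^2
  expect_equal(as.numeric(qvalues(p, pi0 = 1)), p.adjust(p, "BH"))

  # monotone in p, never above 1
  q <- as.numeric(qvalues(p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))

  # pi0 on uniform null p-values lands near 1
  set.seed(41)
  qn <- qvalues(runif(10000))
  expect_gte(attr(qn, "pi0"), 0.8)
  expect_lte(attr(qn, "pi0"), 1.0)

  # short vectors fall back to pi0 = 1
  expect_equal(attr(qvalues(runif(10)), "pi0"), 1)
  expect_error(qvalues(numeric(0)), "empty")
  expect_error(qvalues(c(0.5, 1.5)), "in \\[0, 1\\]")
})

test_that("compare_classes reports planted genes and age-matches normals", {
  sim <- simulate_study(small_config(seed = 51L))
  prep <- preprocess_study(sim$study, pipeline_config(n_perm = 300L,
                                                      seed = 52L))
  meta <- sample_meta(sim$study, "RPE-choroid")
  meta <- meta[match(colnames(prep$log2[["RPE-choroid"]]), meta$sample_id), ]
  spec <- list(phenotype_group = "DryAMD", region_scope = "macula",
               tissue = "RPE-choroid")
  res <- compare_classes(prep$log2[["RPE-choroid"]], meta, spec,
                         n_perm = 300L, seed = 53L)
  planted <- sim$truth$module_membership
  probes <- sim$study$probe_map$probe_id[
    sim$study$probe_map$gene %in% planted$gene[planted$phenotype == "DryAMD"]]
  probes <- intersect(probes, res$probe_id)
  hit <- res[res$probe_id %in% probes, ]
  expect_gt(mean(hit$reported), 0.9)
  expect_true(all(hit$direction[hit$reported] == "up"))

  # young normals are excluded from the reference side: making every normal
  # donor younger than the cutoff leaves no reference samples
  meta_young <- meta
  meta_young$age[meta_young$phenotype == "Normal"] <- 55
  expect_error(
    compare_classes(prep$log2[["RPE-choroid"]], meta_young, spec,
                    n_perm = 50L, seed = 1L),
    "fewer than 2 samples")
})
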