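#' Welch two-sample t-test
#'
#' Unpaired, two-sided t-test with unequal variances (Welch-Satterthwaite
#' degrees of freedom).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df` and `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("degenerate variance: both groups constant with different means")
  }
  sa <- va / length(a); sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Vectorized Welch statistics for all probes (rows of X) for many group
# assignments at once. `memb` is an n-samples x B 0/1 matrix whose columns
# mark group-A membership; column sizes may vary. Returns list of matrices
# (probes x B): t, df.
row_welch_multi <- function(X, memb) {
  n <- ncol(X)
  nA <- colSums(memb)
  nB <- n - nA
  if (any(nA < 2) || any(nB < 2)) stop("each class needs >= 2 members")
  X2 <- X * X
  sA <- X %*% memb
  qA <- X2 %*% memb
  sT <- rowSums(X)
  qT <- rowSums(X2)
  sB <- sT - sA
  qB <- qT - qA
  mA <- sweep(sA, 2, nA, "/")
  mB <- sweep(sB, 2, nB, "/")
  vA <- sweep(qA - sweep(mA^2, 2, nA, "*"), 2, nA - 1, "/")
  vB <- sweep(qB - sweep(mB^2, 2, nB, "*"), 2, nB - 1, "/")
  vA[vA < 0] <- 0   # numerical guard
  vB[vB < 0] <- 0
  seA <- sweep(vA, 2, nA, "/")
  seB <- sweep(vB, 2, nB, "/")
  se2 <- seA + seB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (sweep(seA^2, 2, nA - 1, "/") + sweep(seB^2, 2, nB - 1, "/"))
  t[se2 == 0] <- 0
  df[se2 == 0] <- NA_real_
  list(t = t, df = df)
}

# Label shuffle for one permutation iteration. R's sample.int is a
# Fisher-Yates shuffle; seed-stable under set.seed.
shuffle_labels <- function(n) sample.int(n)

#' Permutation-adjusted p-values for two-class differential expression
#'
#' For each probe, the permuted p-value is the fraction of label
#' permutations whose |t| is at least the observed |t|. One Fisher-Yates
#' shuffle of the label vector is drawn per iteration and applied to all
#' probes.
#'
#' @param data Numeric matrix, probes x samples.
#' @param labels Two-class label vector of length `ncol(data)`; each class
#'   needs >= 2 members.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param add_one If `TRUE`, apply the (k + 1)/(n_perm + 1) correction so
#'   p-values are never exactly zero; default `FALSE` (plain fraction, as in
#'   "fraction of randomized results").
#' @return Numeric vector of permuted p-values, one per probe.
#' @export
permute_p <- function(data, labels, n_perm = 1000L, seed = 1L,
                      add_one = FALSE) {
  stopifnot(is.matrix(data), ncol(data) == length(labels), n_perm >= 1)
  lv <- unique(labels)
  if (length(lv) != 2) stop("exactly two classes required")
  if (min(table(labels)) < 2) stop("each class needs >= 2 members")
  isA <- labels == lv[1]
  obs <- abs(row_welch_multi(data, matrix(as.numeric(isA)))$t[, 1])
  with_stage_seed(seed, "permute_p", {
    count <- numeric(nrow(data))
    block <- 250L
    done <- 0L
    n <- length(labels)
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      memb <- matrix(0, n, b)
      for (i in seq_len(b)) memb[, i] <- as.numeric(isA[shuffle_labels(n)])
      tp <- abs(row_welch_multi(data, memb)$t)
      count <- count + rowSums(tp >= obs)
      done <- done + b
    }
    if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  })
}

#' Storey-Tibshirani q-values
#'
#' Estimates the per-gene false discovery rate: with `m` p-values sorted
#' ascending, `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, capped at 1. The
#' null proportion `pi0` is estimated on the lambda grid 0, 0.05, ..., 0.95
#' with a natural cubic smoothing spline (df = 3) evaluated at the largest
#' lambda, clipped to (0, 1]; vectors shorter than 100 fall back to pi0 = 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param pi0 Optional fixed null proportion (overrides estimation).
#' @param lambda Grid for pi0 estimation.
#' @return Numeric vector of q-values in the input order, with the estimate
#'   attached as attribute `"pi0"`.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0, 0.95, 0.05)) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- if (m < 100) 1 else estimate_pi0(p, lambda)
  }
  o <- order(p)
  p_sorted <- p[o]
  q_sorted <- rev(cummin(rev(pi0 * m * p_sorted / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

estimate_pi0 <- function(p, lambda = seq(0, 0.95, 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) pi0 <- 1   # uninformative estimate; be conservative
  pi0
}

# Full two-class differential expression: Welch t, permuted p, q-values,
# used by the contaminant/gender filters and by compare_classes.
diffexp_two_class <- function(data, labels, n_perm = 1000L, seed = 1L,
                              add_one = FALSE) {
  lv <- unique(labels)
  stopifnot(length(lv) == 2)
  isA <- labels == lv[1]
  w <- row_welch_multi(data, matrix(as.numeric(isA)))
  t_obs <- w$t[, 1]
  df_obs <- w$df[, 1]
  p_nom <- 2 * stats::pt(-abs(t_obs), df_obs)
  p_nom[is.na(p_nom)] <- 1
  pp <- permute_p(data, labels, n_perm = n_perm, seed = seed,
                  add_one = add_one)
  q <- qvalues(pp)
  list(t = t_obs, df = df_obs, p_nominal = p_nom, p_perm = pp,
       q = as.numeric(q), pi0 = attr(q, "pi0"))
}

#' Run one combinatorial class comparison
#'
#' Tests a phenotype group (optionally restricted to one region) against
#' age-matched Normal samples (age >= `age_min`) in the same tissue and
#' region scope. Fold change is the symmetric geometric form
#' `2^|mean(log2 disease) - mean(log2 normal)|`; a probe is "reported" when
#' permuted P < `report_p` and fold change >= `report_fold`.
#'
#' @param expr Log2 matrix (probes x samples) for one tissue, preprocessed.
#' @param meta Metadata data frame aligned to `colnames(expr)` (see
#'   [sample_meta()]).
#' @param spec One row of [enumerate_comparisons()] output (or a list with
#'   `phenotype_group`, `region_scope`, `tissue`).
#' @param report_p,report_fold Reporting thresholds (defaults 0.1, 1.5).
#' @param age_min Minimum age for reference Normal donors (default 60).
#' @param include_mixed If `TRUE` (default) GA-CNV donors are counted in
#'   both the GA and the CNV groups.
#' @param exclude_donors Donor ids excluded from both sides (e.g. anomalous
#'   early-onset cases).
#' @param n_perm,seed Permutation settings.
#' @return Data frame with one row per probe: `probe_id`, `t`, `df`,
#'   `p_nominal`, `p_perm`, `q`, `fold_change`, `direction` (up = higher in
#'   the disease group), `reported`.
#' @export
compare_classes <- function(expr, meta, spec, report_p = 0.1,
                            report_fold = 1.5, age_min = 60,
                            include_mixed = TRUE,
                            exclude_donors = character(),
                            n_perm = 1000L, seed = 1L) {
  stopifnot(ncol(expr) == nrow(meta))
  keep <- !(meta$donor %in% exclude_donors)
  scope_ok <- if (spec$region_scope == "both") rep(TRUE, nrow(meta))
              else meta$region == spec$region_scope
  grp <- phenotype_group_members(meta$phenotype, spec$phenotype_group,
                                 include_mixed)
  disease <- keep & scope_ok & grp
  ref <- keep & scope_ok & meta$phenotype == "Normal" & meta$age >= age_min
  if (sum(disease) < 2 || sum(ref) < 2) {
    stop("comparison ", spec$phenotype_group, "/", spec$region_scope,
         " has fewer than 2 samples on a side after filtering")
  }
  sub <- expr[, disease | ref, drop = FALSE]
  labels <- ifelse(disease[disease | ref], "disease", "normal")
  de <- diffexp_two_class(sub, labels, n_perm = n_perm, seed = seed)
  md <- rowMeans(sub[, labels == "disease", drop = FALSE])
  mn <- rowMeans(sub[, labels == "normal", drop = FALSE])
  fc <- 2^abs(md - mn)
  dir <- ifelse(md >= mn, "up", "down")
  data.frame(probe_id = rownames(expr), t = de$t, df = de$df,
             p_nominal = de$p_nominal, p_perm = de$p_perm, q = de$q,
             fold_change = fc, direction = dir,
             reported = de$p_perm < report_p & fc >= report_fold,
             stringsAsFactors = FALSE)
}

# Which samples belong to a phenotype grouping.
phenotype_group_members <- function(phenotype, group, include_mixed = TRUE) {
  switch(group,
    Global = phenotype != "Normal",
    MD = phenotype %in% c("MD1", "MD2"),
    GA = phenotype == "GA" | (include_mixed & phenotype == "GA-CNV"),
    CNV = phenotype == "CNV" | (include_mixed & phenotype == "GA-CNV"),
    phenotype == group
  )
}
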