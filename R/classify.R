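#' Stratified k-fold assignment
#'
#' Splits samples into `k` folds of near-equal size with per-fold class
#' proportions within one sample of the global proportions.
#'
#' @param labels Class label vector.
#' @param k Number of folds (>= 2); every class must have >= k members.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 3L, seed = 1L) {
  if (k < 2) stop("k must be >= 2 (k = 1 leaves no held-out data)")
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class smaller than k: ", paste(names(tab)[tab < k], collapse = ", "))
  }
  folds <- integer(length(labels))
  with_stage_seed(seed, "folds", {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

#' Prepare classifier features from expression data
#'
#' Takes the top `k` genes of a ranked list, log2-transforms (optional) and
#' median-centers each gene, and optionally appends donor age as a
#' covariate. Features are returned samples x features; the age column is
#' marked via the `"covariate_cols"` attribute so cross-validation can
#' re-standardize it on each training fold.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param genes Ranked character vector of gene ids (best first), all
#'   present in `rownames(expr)`.
#' @param k How many top genes to use; `k = 0` is allowed only with
#'   `include_age = TRUE`.
#' @param include_age Append age as a standardized covariate?
#' @param ages Numeric vector of per-sample ages (required when
#'   `include_age`).
#' @param log2_transform Log2 the expression values first (set `FALSE` if
#'   `expr` is already log2).
#' @return Numeric matrix samples x features.
#' @export
prepare_features <- function(expr, genes, k, include_age = FALSE,
                             ages = NULL, log2_transform = FALSE) {
  if (k == 0 && !include_age) stop("empty feature set: k = 0 without age")
  stopifnot(k <= length(genes))
  missing <- setdiff(genes[seq_len(k)], rownames(expr))
  if (length(missing) > 0) {
    stop("gene(s) not in expression matrix: ", paste(missing, collapse = ", "))
  }
  sub <- expr[genes[seq_len(k)], , drop = FALSE]
  if (log2_transform) sub <- log2(sub)
  med <- apply(sub, 1, stats::median)
  sub <- sweep(sub, 1, med, "-")
  feat <- t(sub)
  cov_cols <- integer(0)
  if (include_age) {
    stopifnot(!is.null(ages), length(ages) == ncol(expr))
    s <- stats::sd(ages)
    z <- if (s > 0) (ages - mean(ages)) / s else ages * 0
    feat <- cbind(feat, age = z)
    cov_cols <- ncol(feat)
  }
  attr(feat, "covariate_cols") <- cov_cols
  feat
}

#' Default margin classifier: linear-kernel SVM
#'
#' The pluggable classifier contract is a list with `fit(x, y)` returning a
#' model and `predict(model, x)` returning labels. The default wraps a
#' linear-kernel support vector machine with default regularization.
#'
#' @param cost Soft-margin cost parameter.
#' @return A classifier contract list.
#' @export
svm_linear_classifier <- function(cost = 1) {
  list(
    fit = function(x, y) {
      e1071::svm(x, factor(y), kernel = "linear", cost = cost, scale = FALSE)
    },
    predict = function(model, x) as.character(stats::predict(model, x))
  )
}

# Majority-vote baseline, used in tests as a degenerate reference.
majority_classifier <- function() {
  list(
    fit = function(x, y) names(which.max(table(y))),
    predict = function(model, x) rep(model, nrow(x))
  )
}

#' Cross-validated classification
#'
#' Fits one model per training fold and evaluates on the held-out fold.
#' Overall accuracy is pooled correct/total; per-fold accuracies and pooled
#' out-of-fold predictions are retained for permutation testing. Covariate
#' columns flagged by [prepare_features()] are re-standardized using
#' training-fold statistics before fitting.
#'
#' @param features Samples x features numeric matrix.
#' @param labels Binary class labels.
#' @param folds Fold assignment from [stratified_folds()].
#' @param classifier Classifier contract (default [svm_linear_classifier()]).
#' @return List of class `classifier_report`: `accuracy` (pooled),
#'   `per_fold_accuracy`, `fold_accuracy_mean`, `predictions`, `folds`,
#'   `labels`.
#' @export
cross_validate <- function(features, labels, folds,
                           classifier = svm_linear_classifier()) {
  stopifnot(nrow(features) == length(labels), length(folds) == length(labels))
  cov_cols <- attr(features, "covariate_cols")
  preds <- character(length(labels))
  per_fold <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    te <- !tr
    xtr <- features[tr, , drop = FALSE]
    xte <- features[te, , drop = FALSE]
    if (length(cov_cols) > 0) {
      for (cc in cov_cols) {
        mu <- mean(xtr[, cc]); s <- stats::sd(xtr[, cc])
        if (s == 0) s <- 1
        xtr[, cc] <- (xtr[, cc] - mu) / s
        xte[, cc] <- (xte[, cc] - mu) / s
      }
    }
    model <- tryCatch(classifier$fit(xtr, labels[tr]),
                      error = function(e) {
                        stop("classifier failed on fold ", f, ": ",
                             conditionMessage(e))
                      })
    p <- classifier$predict(model, xte)
    preds[te] <- p
    per_fold <- c(per_fold, mean(p == labels[te]))
  }
  structure(list(accuracy = mean(preds == labels),
                 per_fold_accuracy = per_fold,
                 fold_accuracy_mean = mean(per_fold),
                 predictions = preds, folds = folds, labels = labels),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("cross-validated accuracy: %.1f%% (%d folds: %s)\n",
              100 * x$accuracy, length(x$per_fold_accuracy),
              paste(sprintf("%.1f%%", 100 * x$per_fold_accuracy),
                    collapse = ", ")))
  if (!is.null(x$permutation_p)) {
    cat(sprintf("permutation p-value: %.4g (%d permutations)\n",
                x$permutation_p, x$n_perm))
  }
  invisible(x)
}

#' Permutation significance of classifier accuracy
#'
#' Permutes the class labels against the fixed out-of-fold predictions and
#' reports the fraction of permutations whose model-averaged accuracy
#' equals or exceeds the observed one. Features and models are never refit:
#' only the label vector is shuffled, which is what makes very deep nulls
#' (the reference analysis used 10^7 permutations) tractable.
#'
#' @param report A `classifier_report` from [cross_validate()], or `NULL` to
#'   fit one from the remaining arguments.
#' @param features,labels,folds,classifier Used only when `report` is NULL.
#' @param n_perm Number of label permutations (>= 1; default 10,000).
#' @param seed Integer seed.
#' @param tie_break `"inclusive"` (default) counts permutations whose
#'   accuracy equals the observed one as exceedances — the conservative
#'   "fraction equal to or exceeding" convention. `"randomized"` splits tie
#'   mass uniformly, the standard construction under which a discrete
#'   permutation p-value is exactly uniform under the null; use it for
#'   calibration studies. Accuracy is a coarse statistic, so ties carry
#'   real mass and the inclusive p is visibly super-uniform near 1.
#' @return The permutation p-value (for `"inclusive"`, a plain fraction
#'   that may be 0). When a report was fitted here it is returned in
#'   attribute `"report"`.
#' @export
permutation_significance <- function(report = NULL, features = NULL,
                                     labels = NULL, folds = NULL,
                                     classifier = svm_linear_classifier(),
                                     n_perm = 10000L, seed = 1L,
                                     tie_break = c("inclusive",
                                                   "randomized")) {
  tie_break <- match.arg(tie_break)
  if (is.null(report)) {
    report <- cross_validate(features, labels, folds, classifier)
  }
  stopifnot(inherits(report, "classifier_report"), n_perm >= 1)
  obs <- report$fold_accuracy_mean
  preds <- report$predictions
  labs <- report$labels
  fold_ids <- sort(unique(report$folds))
  fold_of <- report$folds
  n <- length(labs)
  p <- with_stage_seed(seed, "permsig", {
    gt <- 0L
    eq <- 0L
    tol <- 1e-12
    for (b in seq_len(n_perm)) {
      perm <- labs[sample.int(n)]
      acc <- vapply(fold_ids,
                    function(f) mean(preds[fold_of == f] == perm[fold_of == f]),
                    numeric(1))
      d <- mean(acc) - obs
      if (d > tol) gt <- gt + 1L else if (d > -tol) eq <- eq + 1L
    }
    if (tie_break == "inclusive") {
      (gt + eq) / n_perm
    } else {
      (gt + stats::runif(1) * (eq + 1)) / (n_perm + 1)
    }
  })
  attr(p, "report") <- report
  p
}

#' Iterative top-k biomarker panel selection
#'
#' Runs cross-validated classification on every consecutive head of a ranked
#' gene list (top 1 gene, top 2 genes, ...) and returns the smallest k
#' achieving the maximum accuracy.
#'
#' @param expr Genes x samples matrix (log2 scale).
#' @param ranked_genes Ranked gene ids, best first.
#' @param labels Binary labels per sample.
#' @param k_range Candidate panel sizes (default the full ranked list).
#' @param classifier Classifier contract.
#' @param n_folds Folds for the inner cross-validation (default 3).
#' @param include_age,ages Optional age covariate.
#' @param seed Integer seed (folds are fixed across k so panels are
#'   compared on identical splits).
#' @return List with `best_k`, `accuracies` (named by k), `folds`.
#' @export
select_top_k <- function(expr, ranked_genes, labels,
                         k_range = seq_along(ranked_genes),
                         classifier = svm_linear_classifier(),
                         n_folds = 3L, include_age = FALSE, ages = NULL,
                         seed = 1L) {
  stopifnot(max(k_range) <= length(ranked_genes), min(k_range) >= 1)
  folds <- stratified_folds(labels, k = n_folds, seed = seed)
  acc <- vapply(k_range, function(k) {
    feat <- prepare_features(expr, ranked_genes, k, include_age, ages)
    cross_validate(feat, labels, folds, classifier)$accuracy
  }, numeric(1))
  names(acc) <- k_range
  list(best_k = k_range[which.max(acc)], accuracies = acc, folds = folds)
}
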