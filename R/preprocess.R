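#' Net-intensity scaling
#'
#' Rescales each sample (column) so its signals are expressed as a percentage
#' of the per-sample total times 100,000: `v -> v / sum(column) * 1e5`.
#'
#' @param raw Numeric matrix on the linear scale, all values >= 0.
#' @return Matrix of the same shape; every column sums to 100,000.
#' @export
net_intensity <- function(raw) {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (any(raw < 0)) stop("net_intensity expects non-negative linear values")
  cs <- colSums(raw)
  zero <- cs == 0
  if (any(zero)) {
    nm <- colnames(raw)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("all-zero sample(s): ", paste(nm, collapse = ", "))
  }
  sweep(raw, 2, cs, "/") * 1e5
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same distribution — the
#' cross-column mean of the sorted values — while preserving within-column
#' rank order. Tied values receive the mean of their tied rank means.
#'
#' @param m Numeric matrix, probes x samples.
#' @return Quantile-normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 2) {
    warning("quantile_normalize: single sample, returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Flag cross-tissue contaminant probes
#'
#' A probe is flagged as a contaminant of tissue T when it is (i)
#' differentially enriched in the opposing tissue at Q <= `q`, permuted
#' P <= `p` and fold change >= `fold`, and (ii) its linear-scale mean in T is
#' below `linear_floor` (net-intensity units; the 100 cutoff is about 6.64 in
#' log2 space). Both matrices must share a probe universe and have been
#' quantile-normalized together on the log2 scale.
#'
#' @param tissueA,tissueB Log2 matrices (probes x samples) for the two
#'   tissues, identical probe sets.
#' @param q,p,fold,linear_floor Thresholds (defaults 0.02, 0.01, 1.5, 100).
#' @param n_perm Number of label permutations for the permuted p-value.
#' @param seed Integer seed for the permutations.
#' @param tissue_names Length-2 character vector naming the two tissues in
#'   the returned flag list.
#' @return List of class `contaminant_flags`: `tissue_contaminants` (named
#'   list of probe vectors, one per tissue), and `stats`, a per-probe data
#'   frame of the test statistics.
#' @export
flag_cross_tissue_contaminants <- function(tissueA, tissueB, q = 0.02,
                                           p = 0.01, fold = 1.5,
                                           linear_floor = 100,
                                           n_perm = 1000L, seed = 1L,
                                           tissue_names = tissue_levels()) {
  if (!identical(rownames(tissueA), rownames(tissueB))) {
    stop("probe sets of the two tissues do not match")
  }
  nameA <- tissue_names[1]; nameB <- tissue_names[2]
  combined <- cbind(tissueA, tissueB)
  labels <- rep(c(nameA, nameB), c(ncol(tissueA), ncol(tissueB)))
  de <- diffexp_two_class(combined, labels, n_perm = n_perm, seed = seed)
  meanA_lin <- rowMeans(2^tissueA)
  meanB_lin <- rowMeans(2^tissueB)
  fc <- 2^abs(rowMeans(tissueA) - rowMeans(tissueB))
  sig <- de$q <= q & de$p_perm <= p & fc >= fold
  enrichedA <- sig & meanA_lin > meanB_lin
  enrichedB <- sig & meanB_lin > meanA_lin
  # enriched in the OTHER tissue and near floor here => contaminant here
  contamA <- rownames(tissueA)[enrichedB & meanA_lin < linear_floor]
  contamB <- rownames(tissueA)[enrichedA & meanB_lin < linear_floor]
  stats_df <- data.frame(probe_id = rownames(tissueA), t = de$t,
                         p_perm = de$p_perm, q = de$q, fold_change = fc,
                         mean_linear_A = meanA_lin, mean_linear_B = meanB_lin,
                         stringsAsFactors = FALSE)
  structure(list(tissue_contaminants = stats::setNames(
                   list(contamA, contamB), c(nameA, nameB)),
                 stats = stats_df),
            class = "contaminant_flags")
}

#' Flag gender-specific probes
#'
#' Probes differing between male and female samples (either direction) at
#' Q <= `q`, permuted P <= `p` and fold change >= `fold` in the pooled
#' two-tissue matrix.
#'
#' @param combined Log2 matrix pooling both tissues, quantile normalized.
#' @param genders Character vector of per-sample genders, two levels, each
#'   with >= 2 samples.
#' @param q,p,fold Thresholds (defaults 1e-4, 1e-3, 1.5).
#' @param n_perm,seed Permutation settings.
#' @return Character vector of flagged probe ids, with the statistics table
#'   attached as attribute `"stats"`.
#' @export
flag_gender_genes <- function(combined, genders, q = 1e-4, p = 1e-3,
                              fold = 1.5, n_perm = 1000L, seed = 1L) {
  stopifnot(ncol(combined) == length(genders))
  lv <- unique(genders)
  if (length(lv) < 2) stop("only one gender present; two are required")
  if (length(lv) > 2) stop("more than two gender labels")
  if (min(table(genders)) < 2) stop("need >= 2 samples per gender")
  de <- diffexp_two_class(combined, genders, n_perm = n_perm, seed = seed)
  m1 <- rowMeans(combined[, genders == lv[1], drop = FALSE])
  m2 <- rowMeans(combined[, genders == lv[2], drop = FALSE])
  fc <- 2^abs(m1 - m2)
  hit <- de$q <= q & de$p_perm <= p & fc >= fold
  out <- rownames(combined)[hit]
  attr(out, "stats") <- data.frame(probe_id = rownames(combined), t = de$t,
                                   p_perm = de$p_perm, q = de$q,
                                   fold_change = fc, stringsAsFactors = FALSE)
  out
}

#' Variance filter
#'
#' Removes probes with minimal differential expression across all arrays:
#' sample variance (unbiased, n-1 denominator) less than or equal to
#' `min_var` on the log2 scale. The boundary is inclusive: variance exactly
#' `min_var` is excluded.
#'
#' @param m Log2 matrix, probes x samples.
#' @param min_var Variance floor (default 5).
#' @return Character vector of retained probe ids.
#' @export
variance_filter <- function(m, min_var = 5) {
  stopifnot(is.matrix(m), is.numeric(m))
  v <- apply(m, 1, stats::var)
  rownames(m)[v > min_var]
}
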