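#' Phenotype groupings used in the combinatorial comparisons
#'
#' The six AMD/pre-AMD groupings (MD1, MD2, MD = MD1+MD2, DryAMD, GA, CNV)
#' plus Global (all non-Normal donors combined).
#'
#' @return Character vector of the seven group labels, most specific first.
#' @export
comparison_groups <- function() {
  c("MD1", "MD2", "MD", "DryAMD", "GA", "CNV", "Global")
}

#' Enumerate the combinatorial two-class comparisons
#'
#' Cartesian product of phenotype groupings and region scopes, in
#' deterministic order (groups outer, scopes inner). With the default seven
#' groupings and three scopes this yields the 21 comparisons run per tissue
#' (42 significance-matrix columns over two tissues).
#'
#' @param groups Phenotype groupings (default [comparison_groups()]).
#' @param scopes Region scopes (default macula, extramacula, both).
#' @param tissues Optional tissue vector; when given, the product also runs
#'   over tissues (slowest-varying) and a `tissue` column is included.
#' @return Data frame with columns `phenotype_group`, `region_scope`,
#'   optionally `tissue`, and a unique `comparison_id`.
#' @export
enumerate_comparisons <- function(groups = comparison_groups(),
                                  scopes = c("macula", "extramacula", "both"),
                                  tissues = NULL) {
  stopifnot(length(groups) > 0, length(scopes) > 0)
  base <- data.frame(
    phenotype_group = rep(groups, each = length(scopes)),
    region_scope = rep(scopes, times = length(groups)),
    stringsAsFactors = FALSE
  )
  if (!is.null(tissues)) {
    base <- do.call(rbind, lapply(tissues, function(tis) {
      cbind(tissue = tis, base, stringsAsFactors = FALSE)
    }))
    base$comparison_id <- paste(base$tissue, base$phenotype_group,
                                base$region_scope, sep = "|")
  } else {
    base$comparison_id <- paste(base$phenotype_group, base$region_scope,
                                sep = "|")
  }
  rownames(base) <- NULL
  base
}

#' Build the signed significance-score matrix
#'
#' Converts per-comparison differential expression results into a probe x
#' comparison matrix of significance scores `S_ij = -log10(P_ij)`, signed
#' positive for up- and negative for down-regulation. Only "reported" probes
#' (permuted P below the report threshold and fold change above it)
#' contribute; all other entries are 0. Permutation p-values of exactly 0
#' are capped at `log10(n_perm) + 1` so ordering is preserved without
#' infinities.
#'
#' @param results Named list of [compare_classes()] data frames, one per
#'   comparison; names are the comparison ids (matrix columns, in order).
#' @param n_perm The permutation count used to produce the p-values (sets
#'   the cap for P = 0).
#' @return Numeric matrix, probes x comparisons, of signed scores.
#' @export
significance_matrix <- function(results, n_perm = 1000L) {
  stopifnot(is.list(results), length(results) > 0, !is.null(names(results)))
  probes <- results[[1]]$probe_id
  cap <- log10(n_perm) + 1
  S <- matrix(0, nrow = length(probes), ncol = length(results),
              dimnames = list(probes, names(results)))
  for (j in seq_along(results)) {
    r <- results[[j]]
    if (anyDuplicated(r$probe_id)) {
      stop("duplicate probe entries in comparison ", names(results)[j])
    }
    i <- match(r$probe_id, probes)
    if (anyNA(i)) stop("comparison ", names(results)[j],
                       " contains probes outside the shared universe")
    s <- ifelse(r$p_perm == 0, cap, -log10(r$p_perm))
    s <- pmin(s, cap)
    s <- s * ifelse(r$direction == "up", 1, -1)
    s[!r$reported] <- 0
    S[i, j] <- s
  }
  S
}

#' Collapse probe-level scores to gene level
#'
#' Probes mapping to the same gene are averaged (arithmetic mean per
#' column); probes with no mapping are kept under their probe id.
#'
#' @param S Probe x comparison matrix.
#' @param probe_map Data frame with `probe_id` and `gene`; each probe maps
#'   to at most one gene.
#' @return Gene x comparison matrix.
#' @export
collapse_probes <- function(S, probe_map) {
  stopifnot(is.matrix(S))
  if (is.null(probe_map)) return(S)
  if (anyDuplicated(probe_map$probe_id)) {
    stop("a probe maps to more than one gene")
  }
  gene <- probe_map$gene[match(rownames(S), probe_map$probe_id)]
  gene[is.na(gene)] <- rownames(S)[is.na(gene)]
  agg <- rowsum(S, group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(agg)])
  agg / counts
}

#' Normalize a significance matrix for clustering
#'
#' Three deterministic passes: columns scaled to unit variance, then rows to
#' unit sum of squares, then columns to unit sum of squares. Zero-variance
#' columns are left unscaled with a warning; all-zero rows stay zero.
#'
#' @param S Numeric matrix with >= 2 rows and >= 2 columns.
#' @return Normalized matrix of the same shape.
#' @export
normalize_for_clustering <- function(S) {
  stopifnot(is.matrix(S), nrow(S) >= 2, ncol(S) >= 2)
  v <- apply(S, 2, stats::var)
  if (any(v == 0)) {
    warning("zero-variance column(s) left unscaled: ",
            paste(colnames(S)[v == 0], collapse = ", "))
  }
  sc <- ifelse(v > 0, sqrt(v), 1)
  M <- sweep(S, 2, sc, "/")
  rss <- sqrt(rowSums(M^2))
  M <- sweep(M, 1, ifelse(rss > 0, rss, 1), "/")
  css <- sqrt(colSums(M^2))
  sweep(M, 2, ifelse(css > 0, css, 1), "/")
}

#' Consensus clustering of significance profiles
#'
#' Ensemble of k-means base clusterings with randomized k and random
#' initialization per run. Pairwise co-association (fraction of runs in
#' which two rows share a cluster) is thresholded at `confidence`; connected
#' components of the thresholded co-association graph are the consensus
#' clusters. Rows with identical profiles always co-associate at 1.
#'
#' @param M Numeric matrix (rows are clustered), >= 2 rows.
#' @param runs Ensemble size (>= 2; 500 in the reference configuration).
#' @param confidence Co-association threshold in (0, 1); 0.995 corresponds
#'   to the reference P < 0.005 ensemble confidence.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param k_range Candidate k values for the base k-means runs (default
#'   2 .. min(15, ceiling(sqrt(rows)), rows - 1), the usual k ~ sqrt(n)
#'   heuristic).
#' @return List of class `consensus_clusters`: `membership` (named integer
#'   vector), `coassociation` (symmetric matrix), `runs`, `confidence`.
#' @export
consensus_cluster <- function(M, runs = 500L, confidence = 0.995, seed = 1L,
                              k_range = NULL) {
  stopifnot(is.matrix(M))
  if (nrow(M) < 2) stop("need at least 2 rows to cluster")
  stopifnot(runs >= 2, confidence > 0, confidence < 1)
  n <- nrow(M)
  n_distinct <- nrow(unique(M))
  if (is.null(k_range)) {
    k_range <- 2:max(2, min(15, ceiling(sqrt(n)), n - 1))
  }
  k_range <- k_range[k_range <= max(2, n_distinct)]
  if (length(k_range) == 0) k_range <- 2L
  co <- matrix(0, n, n)
  with_stage_seed(seed, "consensus", {
    for (r in seq_len(runs)) {
      k <- if (length(k_range) == 1) k_range else sample(k_range, 1)
      km <- tryCatch(
        stats::kmeans(M, centers = min(k, n_distinct), nstart = 3,
                      iter.max = 50),
        error = function(e) NULL
      )
      cl <- if (is.null(km)) rep(1L, n) else km$cluster
      same <- outer(cl, cl, "==")
      co <- co + same
    }
  })
  co <- co / runs
  adj <- co >= confidence
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  membership <- igraph::components(g)$membership
  names(membership) <- rownames(M)
  dimnames(co) <- list(rownames(M), rownames(M))
  structure(list(membership = membership, coassociation = co, runs = runs,
                 confidence = confidence),
            class = "consensus_clusters")
}

#' Assemble disease modules from consensus clusters
#'
#' For each cluster the dominant (tissue, phenotype) column group is the one
#' with the largest mean |S| over member genes (scope columns averaged);
#' its sign gives the direction. Clusters sharing a dominant label are
#' merged into one module named `"<tissue> <phenotype> <Up|Down>"`; clusters
#' with no nonzero scores, or smaller than `min_cluster_size`, are dropped.
#' Because significance scores are capped (permutation p-values of 0),
#' clusters significant across every grouping tie at the cap; near-ties
#' (within `tie_tol` of the maximum, same sign) therefore resolve toward
#' the most *general* grouping that is tied — a profile indistinguishable
#' across all phenotypes is a Global signature, not an MD1 one.
#'
#' @param clusters A `consensus_clusters` object or a named membership
#'   vector over the rows of `S`.
#' @param S Gene x comparison significance matrix (rownames = genes).
#' @param comparisons Data frame from `enumerate_comparisons(..., tissues=)`
#'   aligned to `colnames(S)` via `comparison_id`.
#' @param min_cluster_size Clusters below this size are not assembled into
#'   modules (default 2; singletons are usually reporting noise).
#' @param tie_tol Relative tolerance defining a near-tie between column
#'   groups (default 0.02).
#' @param min_scope_support The dominant group must have nonzero mean score
#'   of the dominant sign in at least this many of its scope columns
#'   (default 2). A cluster significant in a single comparison only is
#'   reporting noise, not a phenotype-wide signature: any real
#'   region-scoped signal also appears in the pooled-region comparison.
#' @return Data frame with columns `gene`, `module`, `tissue`, `phenotype`,
#'   `direction`, `cluster`, plus a logical `shared_ga_cnv` marking genes
#'   present in both the GA and the CNV module of a tissue/direction.
#' @export
assemble_modules <- function(clusters, S, comparisons, min_cluster_size = 2L,
                             tie_tol = 0.02, min_scope_support = 2L) {
  membership <- if (inherits(clusters, "consensus_clusters")) {
    clusters$membership
  } else clusters
  stopifnot(!is.null(names(membership)),
            setequal(names(membership), rownames(S)))
  idx <- match(colnames(S), comparisons$comparison_id)
  if (anyNA(idx)) stop("comparison metadata missing for some columns")
  cmp <- comparisons[idx, ]
  grp_key <- paste(cmp$tissue, cmp$phenotype_group, sep = "|")
  # generality: Global subsumes everything, MD subsumes MD1/MD2
  generality <- c(Global = 3, MD = 2)[cmp$phenotype_group]
  generality[is.na(generality)] <- 1

  out <- list()
  for (cl in unique(membership)) {
    genes <- names(membership)[membership == cl]
    if (length(genes) < min_cluster_size) next
    sub <- S[genes, , drop = FALSE]
    if (all(sub == 0)) next   # nothing significant in this cluster
    col_mean <- colMeans(sub)
    g_score <- tapply(col_mean, grp_key, mean)
    g_gen <- tapply(generality, grp_key, max)
    top <- max(abs(g_score))
    tied <- abs(g_score) >= (1 - tie_tol) * top &
      sign(g_score) == sign(g_score[which.max(abs(g_score))])
    cand <- names(g_score)[tied]
    best <- cand[order(-g_gen[cand], -abs(g_score[cand]), cand)][1]
    sgn <- sign(g_score[best])
    support <- sum(grp_key == best & sign(col_mean) == sgn & col_mean != 0)
    if (support < min_scope_support) next
    parts <- strsplit(best, "|", fixed = TRUE)[[1]]
    dir <- if (g_score[best] >= 0) "Up" else "Down"
    out[[length(out) + 1]] <- data.frame(
      gene = genes, tissue = parts[1], phenotype = parts[2], direction = dir,
      cluster = cl, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), module = character(),
                      tissue = character(), phenotype = character(),
                      direction = character(), cluster = integer(),
                      shared_ga_cnv = logical(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df$module <- paste(df$tissue, df$phenotype, df$direction)
  ga <- df$gene[df$phenotype == "GA"]
  cnv <- df$gene[df$phenotype == "CNV"]
  df$shared_ga_cnv <- df$gene %in% intersect(ga, cnv)
  rownames(df) <- NULL
  df[, c("gene", "module", "tissue", "phenotype", "direction", "cluster",
         "shared_ga_cnv")]
}
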