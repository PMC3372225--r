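#' Interaction graph container
#'
#' An undirected gene-symbol graph with a per-edge source tag and score.
#' Edges are stored canonically (node1 < node2); self-edges and duplicate
#' unordered pairs are rejected.
#'
#' @param edges Data frame with columns `node1`, `node2` and optionally
#'   `score` (in [0, 1], default 1) and `source` (default "synthetic").
#' @param nodes Optional node universe (isolated nodes allowed); defaults
#'   to the nodes appearing in `edges`.
#' @return An `interaction_graph` list with `nodes` and `edges`.
#' @export
interaction_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("node1", "node2") %in% names(edges)))
  if (is.null(edges$score)) edges$score <- rep(1, nrow(edges))
  if (is.null(edges$source)) edges$source <- rep("synthetic", nrow(edges))
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("edge scores must be in [0, 1]")
  }
  if (any(edges$node1 == edges$node2)) stop("self-edges are not allowed")
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  edges$node1 <- a
  edges$node2 <- b
  key <- paste(a, b)
  if (anyDuplicated(key)) stop("duplicate unordered edge(s) present")
  if (is.null(nodes)) nodes <- sort(unique(c(a, b)))
  else {
    outside <- setdiff(unique(c(a, b)), nodes)
    if (length(outside) > 0) stop("edge endpoint(s) outside node set: ",
                                  paste(utils::head(outside, 5), collapse = ", "))
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  src <- table(x$edges$source)
  cat("  sources:", paste(sprintf("%s (%d)", names(src), src),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Average node degree of a gene set
#'
#' The connectivity-enrichment proxy `D = 2 * edges / nodes`, computed on
#' the subgraph induced by the module genes that match graph nodes.
#'
#' @param genes Character vector of gene symbols.
#' @param graph An [interaction_graph()].
#' @return `D`, with the matched node count in attribute `"n_matched"`.
#' @export
average_node_degree <- function(genes, graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  matched <- intersect(genes, graph$nodes)
  if (length(matched) == 0) stop("empty module in graph: no genes matched")
  inset <- graph$edges$node1 %in% matched & graph$edges$node2 %in% matched
  d <- 2 * sum(inset) / length(matched)
  attr(d, "n_matched") <- length(matched)
  d
}

#' Monte-Carlo null model for average node degree
#'
#' For each module size in `sizes`, draws `reps` uniform node samples
#' without replacement, records the null distribution of `D`, takes the
#' (1 - alpha) quantile per size for each alpha, and fits an ordinary
#' least-squares line E(D) = slope * nodes + intercept through the per-size
#' quantiles (one line per alpha). The reference analysis used sizes 50,
#' 100, 200, 300, 400 with 10,000 samples each.
#'
#' @param graph An [interaction_graph()].
#' @param sizes Node-sample sizes (all <= number of graph nodes).
#' @param reps Samples per size (>= 100).
#' @param alphas Significance levels (default 0.05 and 0.01).
#' @param seed Integer seed.
#' @return List of class `degree_null_model`: `sizes`, `quantiles`
#'   (alpha x size matrix), `fits` (per alpha: slope, intercept, r2),
#'   `null_mean` per size, `reps`.
#' @export
monte_carlo_degree_null <- function(graph, sizes = c(50, 100, 200, 300, 400),
                                    reps = 10000L, alphas = c(0.05, 0.01),
                                    seed = 1L) {
  stopifnot(inherits(graph, "interaction_graph"), reps >= 100)
  n_nodes <- length(graph$nodes)
  if (max(sizes) > n_nodes) {
    stop("sample size ", max(sizes), " exceeds node count ", n_nodes)
  }
  sizes <- sort(sizes)
  u <- match(graph$edges$node1, graph$nodes)
  v <- match(graph$edges$node2, graph$nodes)
  qmat <- matrix(NA_real_, nrow = length(alphas), ncol = length(sizes),
                 dimnames = list(paste0("alpha_", alphas), sizes))
  null_mean <- numeric(length(sizes))
  with_stage_seed(seed, "degreenull", {
    memb <- logical(n_nodes)
    for (si in seq_along(sizes)) {
      nsz <- sizes[si]
      D <- numeric(reps)
      for (r in seq_len(reps)) {
        s <- sample.int(n_nodes, nsz)
        memb[s] <- TRUE
        D[r] <- 2 * sum(memb[u] & memb[v]) / nsz
        memb[s] <- FALSE
      }
      null_mean[si] <- mean(D)
      for (ai in seq_along(alphas)) {
        qmat[ai, si] <- stats::quantile(D, 1 - alphas[ai], names = FALSE)
      }
    }
  })
  fits <- lapply(seq_along(alphas), function(ai) {
    fit <- stats::lm(qmat[ai, ] ~ sizes)
    # on degenerate (deterministic-D) graphs the fit is exact; the
    # perfect-fit warning from summary.lm is expected there
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2)
  })
  names(fits) <- paste0("alpha_", alphas)
  structure(list(sizes = sizes, alphas = alphas, quantiles = qmat,
                 fits = fits, null_mean = null_mean, reps = reps),
            class = "degree_null_model")
}

#' Connectivity enrichment of one module
#'
#' Compares the module's observed average node degree to the expected null
#' degree E(D) evaluated at the module's matched-node count via the fitted
#' per-alpha line; the module is enriched at alpha when D > E(D).
#'
#' @param genes Module gene set (or a data frame with a `gene` column).
#' @param graph An [interaction_graph()]; must be the graph the null model
#'   was fitted on.
#' @param null A `degree_null_model` from [monte_carlo_degree_null()].
#' @param name Optional module name for the report.
#' @return One-row data frame: `module`, `n_nodes`, `D`, one `ED_*` and one
#'   `enriched_*` column per alpha.
#' @export
module_enrichment <- function(genes, graph, null, name = "module") {
  stopifnot(inherits(null, "degree_null_model"))
  if (is.data.frame(genes)) genes <- genes$gene
  d <- average_node_degree(genes, graph)
  n <- attr(d, "n_matched")
  if (n < min(null$sizes) || n > max(null$sizes)) {
    warning("module size ", n, " outside fitted range [", min(null$sizes),
            ", ", max(null$sizes), "]; E(D) is extrapolated")
  }
  row <- data.frame(module = name, n_nodes = n, D = as.numeric(d),
                    stringsAsFactors = FALSE)
  for (ai in seq_along(null$alphas)) {
    fit <- null$fits[[ai]]
    ed <- fit$intercept + fit$slope * n
    row[[paste0("ED_", null$alphas[ai])]] <- ed
    row[[paste0("enriched_", null$alphas[ai])]] <- as.numeric(d) > ed
  }
  row
}

#' Assemble an interactome from multiple edge sources
#'
#' Filters each source by its score threshold, removes self-edges, and
#' deduplicates unordered pairs under a source-precedence ("dominance")
#' series: each pair keeps exactly the annotation of its highest-precedence
#' source (curated PPI > pathway-tool edges > database/experimental
#' evidence > text-mining).
#'
#' @param edge_tables Data frame (or list of data frames, rbind-ed) with
#'   columns `node1`, `node2`, `score`, `source`.
#' @param score_threshold Named numeric vector of per-source minimum scores
#'   (sources absent from the vector are unthresholded). The conventional
#'   database threshold is 0.7 ("high confidence"); 0.4 admits
#'   medium-confidence edges.
#' @param precedence Character vector, most dominant first; must cover every
#'   source present.
#' @return An [interaction_graph()].
#' @export
assemble_interactome <- function(edge_tables,
                                 score_threshold = c(`STRING-db/exp` = 0.7,
                                                     `STRING-text` = 0.7),
                                 precedence = c("PPI", "IPA",
                                                "STRING-db/exp",
                                                "STRING-text", "synthetic")) {
  if (is.data.frame(edge_tables)) edge_tables <- list(edge_tables)
  edges <- do.call(rbind, lapply(edge_tables, function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    stopifnot(all(c("node1", "node2", "source") %in% names(df)))
    if (is.null(df$score)) df$score <- 1
    df[, c("node1", "node2", "score", "source")]
  }))
  unknown <- setdiff(unique(edges$source), precedence)
  if (length(unknown) > 0) {
    stop("unknown edge source tag(s): ", paste(unknown, collapse = ", "),
         "; precedence covers: ", paste(precedence, collapse = " > "))
  }
  thr <- score_threshold[edges$source]
  thr[is.na(thr)] <- 0
  edges <- edges[edges$score >= thr, , drop = FALSE]
  edges <- edges[edges$node1 != edges$node2, , drop = FALSE]
  a <- pmin(edges$node1, edges$node2)
  b <- pmax(edges$node1, edges$node2)
  rank <- match(edges$source, precedence)
  o <- order(a, b, rank)
  edges <- edges[o, , drop = FALSE]
  key <- paste(a[o], b[o])
  interaction_graph(edges[!duplicated(key), , drop = FALSE])
}

#' One-sided gene-set overlap test
#'
#' Upper-tail hypergeometric probability of observing at least `k` genes in
#' the overlap of a size-`m` set and a size-`K` set drawn from a universe of
#' `N` genes (Fisher's exact test for enrichment).
#'
#' @param k Overlap count.
#' @param m Size of set A.
#' @param K Size of set B.
#' @param N Universe size (e.g. the 19,542 annotated genes on the array).
#' @return P(X >= k) with X ~ Hypergeometric(N, K, m).
#' @export
fisher_overlap <- function(k, m, K, N) {
  if (k < 0 || m < 0 || K < 0 || N < 1 || k > min(m, K) || m > N || K > N) {
    stop("inconsistent counts: need 0 <= k <= min(m, K) <= N")
  }
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Write a network as SIF plus node attributes
#'
#' @param graph An [interaction_graph()].
#' @param sif_path Output SIF path (`node1 <source> node2` per line).
#' @param attr_path Optional node-attribute TSV path.
#' @param node_attrs Optional data frame with a `node` column and attribute
#'   columns.
#' @return `sif_path`, invisibly.
#' @export
write_sif <- function(graph, sif_path, attr_path = NULL, node_attrs = NULL) {
  stopifnot(inherits(graph, "interaction_graph"))
  lines <- paste(graph$edges$node1, graph$edges$source, graph$edges$node2,
                 sep = "\t")
  writeLines(lines, sif_path)
  if (!is.null(attr_path) && !is.null(node_attrs)) {
    write_tsv(node_attrs, attr_path)
  }
  invisible(sif_path)
}
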