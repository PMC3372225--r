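#' Pipeline configuration
#'
#' All stage thresholds of the end-to-end analysis, defaulting to the
#' reference study's printed values. Every field can be overridden.
#'
#' @param contaminant_q,contaminant_p,contaminant_fold Cross-tissue
#'   contaminant thresholds (Q <= 0.02, permuted P <= 0.01, fold >= 1.5).
#' @param linear_floor Net-intensity mean below which an opposing-tissue
#'   enriched probe is a contaminant (100, about 6.64 in log2 space).
#' @param gender_q,gender_p,gender_fold Gender-contaminant thresholds
#'   (Q <= 1e-4, permuted P <= 1e-3, fold >= 1.5).
#' @param variance_floor Linear-scale sample-variance floor; probes at or
#'   below it are excluded (5).
#' @param report_p,report_fold Reporting rule for the class comparisons
#'   (permuted P < 0.1, fold >= 1.5).
#' @param age_min Minimum reference-donor age (60).
#' @param include_mixed Count GA-CNV donors in both GA and CNV groups.
#' @param exclude_donors Donor ids dropped before analysis.
#' @param n_perm Label permutations for differential expression (1000).
#' @param cluster_runs,cluster_confidence Consensus-clustering ensemble size
#'   (500) and co-association threshold (0.995, i.e. P < 0.005).
#' @param classifier_k Biomarker panel size (20).
#' @param n_folds Cross-validation folds (3).
#' @param classify_n_perm Label permutations for classifier significance
#'   (default 10,000; the reference analysis used 10^7).
#' @param classify_include_age Append donor age to the classifier features.
#' @param null_sizes,null_reps,alphas Degree-null Monte-Carlo grid
#'   (50-400 nodes, 10,000 reps, alpha 0.05/0.01).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(contaminant_q = 0.02, contaminant_p = 0.01,
                            contaminant_fold = 1.5, linear_floor = 100,
                            gender_q = 1e-4, gender_p = 1e-3,
                            gender_fold = 1.5, variance_floor = 5,
                            report_p = 0.1, report_fold = 1.5, age_min = 60,
                            include_mixed = TRUE,
                            exclude_donors = character(),
                            n_perm = 1000L, cluster_runs = 500L,
                            cluster_confidence = 0.995, classifier_k = 20L,
                            n_folds = 3L, classify_n_perm = 10000L,
                            classify_include_age = FALSE,
                            null_sizes = c(50, 100, 200, 300, 400),
                            null_reps = 10000L, alphas = c(0.05, 0.01),
                            seed = 1L) {
  cfg <- list(contaminant_q = contaminant_q, contaminant_p = contaminant_p,
              contaminant_fold = contaminant_fold,
              linear_floor = linear_floor, gender_q = gender_q,
              gender_p = gender_p, gender_fold = gender_fold,
              variance_floor = variance_floor, report_p = report_p,
              report_fold = report_fold, age_min = age_min,
              include_mixed = include_mixed, exclude_donors = exclude_donors,
              n_perm = as.integer(n_perm),
              cluster_runs = as.integer(cluster_runs),
              cluster_confidence = cluster_confidence,
              classifier_k = as.integer(classifier_k),
              n_folds = as.integer(n_folds),
              classify_n_perm = as.integer(classify_n_perm),
              classify_include_age = classify_include_age,
              null_sizes = null_sizes, null_reps = as.integer(null_reps),
              alphas = alphas, seed = as.integer(seed))
  probs <- c("contaminant_q", "contaminant_p", "gender_q", "gender_p",
             "report_p", "cluster_confidence")
  for (f in probs) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must be in (0, 1)")
  }
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (cfg$classify_n_perm < 1) stop("classify_n_perm must be >= 1")
  if (cfg$cluster_runs < 2) stop("cluster_runs must be >= 2")
  if (cfg$n_folds < 2) stop("n_folds must be >= 2")
  if (any(c(cfg$contaminant_fold, cfg$gender_fold, cfg$report_fold) < 1)) {
    stop("fold-change thresholds must be >= 1")
  }
  structure(cfg, class = "pipeline_config")
}

log2_floor <- function(m) log2(pmax(m, .Machine$double.eps))

#' Preprocess a study: normalize and filter contaminants
#'
#' Applies net-intensity scaling, flags cross-tissue and gender
#' contaminants on the jointly quantile-normalized log2 matrix, then
#' quantile-normalizes each tissue separately, log2-transforms, and removes
#' flagged probes and probes failing the linear-scale variance floor.
#'
#' @param study An [expression_study()] with both tissues on the linear
#'   net-intensity scale.
#' @param config A [pipeline_config()].
#' @return List: `log2` (per-tissue filtered log2 matrices), `flags`
#'   (contaminant flags), `gender_probes`, `retained` (per-tissue probe
#'   vectors), `counts` (per-stage probe tallies).
#' @export
preprocess_study <- function(study, config = pipeline_config()) {
  stopifnot(inherits(study, "expression_study"))
  tissues <- names(study$expr)
  stopifnot(length(tissues) == 2)
  lin <- lapply(study$expr, net_intensity)
  probes <- rownames(lin[[1]])
  if (!identical(probes, rownames(lin[[2]]))) {
    stop("tissue matrices must share one probe universe")
  }
  combined <- quantile_normalize(cbind(lin[[1]], lin[[2]]))
  combined_log2 <- log2_floor(combined)
  colA <- seq_len(ncol(lin[[1]]))
  flags <- flag_cross_tissue_contaminants(
    combined_log2[, colA, drop = FALSE],
    combined_log2[, -colA, drop = FALSE],
    q = config$contaminant_q, p = config$contaminant_p,
    fold = config$contaminant_fold, linear_floor = config$linear_floor,
    n_perm = config$n_perm, seed = config$seed, tissue_names = tissues
  )
  genders <- study$meta$gender[match(colnames(combined), study$meta$sample_id)]
  gender_probes <- flag_gender_genes(
    combined_log2, genders, q = config$gender_q, p = config$gender_p,
    fold = config$gender_fold, n_perm = config$n_perm,
    seed = config$seed + 1L
  )
  out_log2 <- list()
  retained <- list()
  counts <- list(probes_in = length(probes))
  for (tis in tissues) {
    qn <- quantile_normalize(lin[[tis]])
    keep_var <- variance_filter(qn, config$variance_floor)
    drop <- union(flags$tissue_contaminants[[tis]], gender_probes)
    keep <- setdiff(keep_var, drop)
    retained[[tis]] <- keep
    out_log2[[tis]] <- log2_floor(qn[keep, , drop = FALSE])
    counts[[paste0("contaminants_", tis)]] <-
      length(flags$tissue_contaminants[[tis]])
    counts[[paste0("low_variance_", tis)]] <- length(probes) - length(keep_var)
    counts[[paste0("retained_", tis)]] <- length(keep)
  }
  counts$gender_probes <- length(gender_probes)
  list(log2 = out_log2, flags = flags,
       gender_probes = as.character(gender_probes), retained = retained,
       counts = counts)
}

#' Run all combinatorial comparisons for a study
#'
#' @param prep Output of [preprocess_study()].
#' @param study The [expression_study()].
#' @param config A [pipeline_config()].
#' @return Named list of [compare_classes()] tables keyed by comparison id,
#'   with the comparison table attached as attribute `"comparisons"`.
#' @export
run_comparisons <- function(prep, study, config = pipeline_config()) {
  tissues <- names(prep$log2)
  cmp <- enumerate_comparisons(tissues = tissues)
  results <- list()
  for (i in seq_len(nrow(cmp))) {
    tis <- cmp$tissue[i]
    meta <- sample_meta(study, tis)
    res <- tryCatch(
      compare_classes(prep$log2[[tis]], meta, cmp[i, ],
                      report_p = config$report_p,
                      report_fold = config$report_fold,
                      age_min = config$age_min,
                      include_mixed = config$include_mixed,
                      exclude_donors = config$exclude_donors,
                      n_perm = config$n_perm,
                      seed = config$seed + 10L + i),
      error = function(e) stop("comparison ", cmp$comparison_id[i],
                               " failed: ", conditionMessage(e)))
    results[[cmp$comparison_id[i]]] <- res
  }
  attr(results, "comparisons") <- cmp
  results
}

# Per-tissue significance matrices share no probes after filtering, so the
# 42-column matrix is assembled gene-wise: probe-level scores are collapsed
# per tissue, then joined on gene over the union.
build_significance_matrix <- function(results, probe_map, config) {
  cmp <- attr(results, "comparisons")
  tissues <- unique(cmp$tissue)
  per_tissue <- lapply(tissues, function(tis) {
    ids <- cmp$comparison_id[cmp$tissue == tis]
    S <- significance_matrix(results[ids], n_perm = config$n_perm)
    collapse_probes(S, probe_map)
  })
  genes <- sort(unique(unlist(lapply(per_tissue, rownames))))
  S <- matrix(0, nrow = length(genes),
              ncol = sum(vapply(per_tissue, ncol, integer(1))),
              dimnames = list(genes, unlist(lapply(per_tissue, colnames))))
  for (st in per_tissue) S[rownames(st), colnames(st)] <- st
  S
}

#' Run the full disease-module discovery pipeline
#'
#' Executes preprocess, the combinatorial comparisons, significance-matrix
#' construction, consensus clustering into disease modules, biomarker
#' cross-validation, and (when a background graph is supplied) connectivity
#' enrichment. With `outdir` set, every stage's table is written as TSV
#' along with a JSON manifest of seeds, configuration and file checksums;
#' identical study + config yield identical manifests.
#'
#' @param study An [expression_study()] on the linear net-intensity scale.
#' @param config A [pipeline_config()].
#' @param graph Optional [interaction_graph()] for enrichment.
#' @param signature_module Module name whose top genes feed the classifier;
#'   default the first tissue's "Global Up" module.
#' @param outdir Optional output directory.
#' @return List of class `pipeline_run`: `prep`, `diffexp`, `S`, `clusters`,
#'   `modules`, `classifier`, `enrichment`, `null_model`, `config`,
#'   `manifest`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), graph = NULL,
                         signature_module = NULL, outdir = NULL) {
  stopifnot(inherits(study, "expression_study"),
            inherits(config, "pipeline_config"))
  prep <- preprocess_study(study, config)
  results <- run_comparisons(prep, study, config)
  cmp <- attr(results, "comparisons")
  S <- build_significance_matrix(results, study$probe_map, config)
  nz <- rowSums(S != 0) > 0
  S_sig <- S[nz, , drop = FALSE]
  modules <- data.frame()
  clusters <- NULL
  if (nrow(S_sig) >= 2) {
    M <- suppressWarnings(normalize_for_clustering(S_sig))
    clusters <- consensus_cluster(M, runs = config$cluster_runs,
                                  confidence = config$cluster_confidence,
                                  seed = config$seed + 100L)
    modules <- assemble_modules(clusters, S_sig, cmp)
  }

  classifier_report <- NULL
  tissues <- names(prep$log2)
  if (is.null(signature_module)) {
    signature_module <- paste(tissues[1], "Global Up")
  }
  sig_genes <- modules$gene[modules$module == signature_module]
  if (length(sig_genes) >= 1) {
    tis <- modules$tissue[modules$module == signature_module][1]
    glob_cols <- cmp$comparison_id[cmp$tissue == tis &
                                   cmp$phenotype_group == "Global"]
    rank_score <- rowMeans(abs(S_sig[sig_genes, glob_cols, drop = FALSE]))
    ranked <- sig_genes[order(-rank_score)]
    k <- min(config$classifier_k, length(ranked))
    gene_expr <- gene_level_expression(prep$log2[[tis]], study$probe_map)
    meta <- sample_meta(study, tis)
    labels <- ifelse(meta$phenotype == "Normal", "Normal", "AMD")
    if (min(table(labels)) >= config$n_folds) {
      feat <- prepare_features(gene_expr, ranked, k,
                               include_age = config$classify_include_age,
                               ages = meta$age)
      folds <- stratified_folds(labels, k = config$n_folds,
                                seed = config$seed + 200L)
      classifier_report <- cross_validate(feat, labels, folds)
      pp <- permutation_significance(classifier_report,
                                     n_perm = config$classify_n_perm,
                                     seed = config$seed + 201L)
      classifier_report$permutation_p <- as.numeric(pp)
      classifier_report$n_perm <- config$classify_n_perm
      classifier_report$k_used <- k
      classifier_report$genes <- ranked[seq_len(k)]
    }
  }

  enrichment <- NULL
  null_model <- NULL
  if (!is.null(graph) && nrow(modules) > 0) {
    sizes <- config$null_sizes[config$null_sizes <= length(graph$nodes)]
    null_model <- monte_carlo_degree_null(graph, sizes = sizes,
                                          reps = config$null_reps,
                                          alphas = config$alphas,
                                          seed = config$seed + 300L)
    enrichment <- do.call(rbind, lapply(split(modules, modules$module),
      function(md) {
        tryCatch(
          suppressWarnings(module_enrichment(md$gene, graph, null_model,
                                             name = md$module[1])),
          error = function(e) NULL)
      }))
    if (!is.null(enrichment)) rownames(enrichment) <- NULL
  }

  run <- structure(list(prep = prep, diffexp = results, S = S,
                        clusters = clusters, modules = modules,
                        classifier = classifier_report,
                        enrichment = enrichment, null_model = null_model,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(outdir)) run$manifest <- write_pipeline_run(run, outdir)
  run
}

gene_level_expression <- function(expr, probe_map) {
  if (is.null(probe_map)) return(expr)
  gene <- probe_map$gene[match(rownames(expr), probe_map$probe_id)]
  gene[is.na(gene)] <- rownames(expr)[is.na(gene)]
  agg <- rowsum(expr, group = gene, reorder = TRUE)
  agg / as.vector(table(gene)[rownames(agg)])
}

write_pipeline_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
  }
  w(run$prep$flags$stats, "contaminant_stats.tsv")
  flagged <- do.call(rbind, c(
    lapply(names(run$prep$flags$tissue_contaminants), function(tis) {
      pr <- run$prep$flags$tissue_contaminants[[tis]]
      if (length(pr) == 0) return(NULL)
      data.frame(probe_id = pr, flag_type = paste0("contaminant_", tis),
                 stringsAsFactors = FALSE)
    }),
    list(if (length(run$prep$gender_probes) > 0) {
      data.frame(probe_id = run$prep$gender_probes, flag_type = "gender",
                 stringsAsFactors = FALSE)
    })))
  if (is.null(flagged)) {
    flagged <- data.frame(probe_id = character(), flag_type = character())
  }
  w(flagged, "flags.tsv")
  de <- do.call(rbind, lapply(names(run$diffexp), function(id) {
    r <- run$diffexp[[id]][run$diffexp[[id]]$reported, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    cbind(comparison = id, r, stringsAsFactors = FALSE)
  }))
  if (is.null(de)) de <- data.frame(comparison = character())
  w(de, "reported_genes.tsv")
  w(data.frame(gene = rownames(run$S), run$S, check.names = FALSE),
    "significance_matrix.tsv")
  w(run$modules, "modules.tsv")
  if (!is.null(run$classifier)) {
    w(data.frame(k_used = run$classifier$k_used,
                 accuracy = run$classifier$accuracy,
                 fold_accuracy_mean = run$classifier$fold_accuracy_mean,
                 permutation_p = run$classifier$permutation_p,
                 n_perm = run$classifier$n_perm),
      "classifier_report.tsv")
  }
  if (!is.null(run$enrichment)) w(run$enrichment, "module_enrichment.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("amdmodules")),
    seed = run$config$seed,
    config = unclass(run$config),
    probe_counts = run$prep$counts,
    files = as.list(tools::md5sum(unlist(paths)))
  )
  names(manifest$files) <- names(paths)
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
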