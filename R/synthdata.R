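#' @keywords internal
"_PACKAGE"

#' Phenotype vocabulary
#'
#' Canonical AMD phenotype classes: Normal, pre-AMD (MD1, hard macular
#' drusen), sub-clinical pre-AMD (MD2, soft drusen), Dry AMD, geographic
#' atrophy (GA), choroidal neovascularization (CNV, wet AMD), and mixed
#' GA-CNV.
#'
#' @return Character vector of allowed phenotype labels.
#' @export
phenotype_levels <- function() {
  c("Normal", "MD1", "MD2", "DryAMD", "GA", "CNV", "GA-CNV")
}

#' Tissue vocabulary
#' @return Character vector of the two profiled tissues.
#' @export
tissue_levels <- function() c("RPE-choroid", "retina")

#' Region vocabulary
#' @return Character vector of tissue-punch regions.
#' @export
region_levels <- function() c("macula", "extramacula")

# Default planted design: tissue-wide (both-region) modules for three AMD
# phenotypes plus a Global disease signature, all at 1.5 log2 effect.
# Region-restricted planting is supported via the `region` column; at this
# effect size a macula-only module is diluted to a ~1.7-fold shift in the
# pooled-region comparisons, right at the 1.5-fold reporting gate, so its
# recovery is intentionally partial (see the methods vignette).
default_planted_modules <- function() {
  data.frame(
    phenotype = c("DryAMD", "CNV", "GA", "Global"),
    region    = "both",
    direction = c("Up", "Up", "Down", "Up"),
    n_genes   = c(30L, 30L, 30L, 20L),
    effect    = c(1.5, 1.5, 1.5, 1.5),
    tissue    = "RPE-choroid",
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic two-tissue, two-region AMD cohort generator.
#' Defaults reproduce the donor-per-class counts of the study design
#' (31 Normal, 7 MD1, 4 MD2, 17 DryAMD, 2 GA, 4 CNV, 3 GA-CNV) with a small
#' set of planted disease modules at 1.5 log2 effect.
#'
#' @param donors_per_class Named integer vector of donors per phenotype class.
#'   `Normal` must be at least 1; other classes may be 0.
#' @param n_probes Number of probes; probes map many-to-one onto genes.
#' @param n_genes Number of genes (`n_genes <= n_probes`).
#' @param planted_modules Data frame with columns `phenotype` (a phenotype
#'   label or `"Global"` for all non-Normal donors), `region` (`"macula"`,
#'   `"extramacula"` or `"both"`), `direction` (`"Up"`/`"Down"`), `n_genes`,
#'   `effect` (log2 shift, > 0) and `tissue`.
#' @param contaminant_fraction Fraction of genes that are tissue-exclusive
#'   (half enriched in each tissue), in [0, 1).
#' @param gender_gene_count Number of gender-specific genes.
#' @param gender_effect Log2 shift of gender-specific genes.
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param baseline_mean,baseline_sd Log2 mean and spread of per-gene baseline
#'   expression.
#' @param contaminant_mean,contaminant_sd Log2 mean/spread of a contaminant
#'   gene in its own tissue.
#' @param contaminant_floor Linear mean of a contaminant gene in the opposing
#'   tissue (kept well under the 100 net-intensity cutoff).
#' @param age_range Numeric length-2 donor age range in years.
#' @param seed Integer seed; identical seeds give identical cohorts.
#'
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(donors_per_class = c(Normal = 31L, MD1 = 7L,
                                               MD2 = 4L, DryAMD = 17L,
                                               GA = 2L, CNV = 4L,
                                               `GA-CNV` = 3L),
                          n_probes = 2400L,
                          n_genes = 2000L,
                          planted_modules = default_planted_modules(),
                          contaminant_fraction = 0.05,
                          gender_gene_count = 10L,
                          gender_effect = 3,
                          noise_sd = 0.5,
                          baseline_mean = 6,
                          baseline_sd = 1.5,
                          contaminant_mean = 9,
                          contaminant_sd = 0.5,
                          contaminant_floor = 20,
                          age_range = c(60, 95),
                          seed = 1L) {
  stopifnot(is.numeric(donors_per_class), !is.null(names(donors_per_class)))
  unknown <- setdiff(names(donors_per_class), phenotype_levels())
  if (length(unknown) > 0) {
    stop("unknown phenotype class(es): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(phenotype_levels(), collapse = ", "))
  }
  if (is.na(donors_per_class["Normal"]) || donors_per_class["Normal"] < 1) {
    stop("no reference class: at least one Normal donor is required")
  }
  if (any(donors_per_class < 0)) stop("donor counts must be >= 0")
  if (n_genes > n_probes) stop("n_genes must not exceed n_probes")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)")
  }
  pm <- as.data.frame(planted_modules, stringsAsFactors = FALSE)
  if (nrow(pm) > 0) {
    needed <- c("phenotype", "region", "direction", "n_genes", "effect")
    if (!all(needed %in% names(pm))) {
      stop("planted_modules needs columns: ", paste(needed, collapse = ", "))
    }
    if (is.null(pm$tissue)) pm$tissue <- "RPE-choroid"
    if (any(pm$effect <= 0)) stop("planted module effect sizes must be > 0")
    bad <- setdiff(pm$phenotype, c(phenotype_levels(), "Global"))
    if (length(bad) > 0) stop("unknown planted phenotype: ", bad[1])
    stopifnot(all(pm$region %in% c(region_levels(), "both")),
              all(pm$direction %in% c("Up", "Down")),
              all(pm$tissue %in% tissue_levels()))
  }
  structure(list(donors_per_class = donors_per_class,
                 n_probes = as.integer(n_probes),
                 n_genes = as.integer(n_genes),
                 planted_modules = pm,
                 contaminant_fraction = contaminant_fraction,
                 gender_gene_count = as.integer(gender_gene_count),
                 gender_effect = gender_effect,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 contaminant_mean = contaminant_mean,
                 contaminant_sd = contaminant_sd,
                 contaminant_floor = contaminant_floor,
                 age_range = age_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Run `expr` with a private RNG stream seeded from (seed, stage) so each
# generator stage is reproducible independently of calling order.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  # fold the stage name into the seed, staying under 2^31
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  set.seed((as.integer(seed) %% 1000003L) * 1009L + h %% 100003L)
  expr
}

#' Simulate a two-tissue AMD expression study with known truth
#'
#' Generates one sample per (donor, tissue, region). Baseline log2 expression
#' is drawn per gene; planted modules shift class means by the configured
#' log2 effect in the configured phenotype, region and tissue; contaminant
#' genes are expressed in one tissue and near floor in the other;
#' gender-specific genes are shifted between male and female donors. Values
#' are returned on the linear net-intensity scale (each sample sums to
#' 100,000).
#'
#' @param config A [cohort_config()].
#' @return A list with `study` (an [expression_study()]) and `truth` (a
#'   `synthetic_truth` list: `module_membership` data frame, `contaminants`
#'   per tissue, `gender_genes`, `effect_sizes`).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  dpc <- config$donors_per_class
  classes <- rep(names(dpc), times = dpc)
  n_donor <- length(classes)

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  probes <- sprintf("P%05d", seq_len(config$n_probes))
  # first n_genes probes map 1:1; extras duplicate randomly chosen genes
  probe_gene <- with_stage_seed(config$seed, "probemap", {
    extra <- config$n_probes - config$n_genes
    c(genes, if (extra > 0) sample(genes, extra, replace = TRUE))
  })
  probe_map <- data.frame(probe_id = probes, gene = probe_gene,
                          stringsAsFactors = FALSE)

  # assign special gene roles from a disjoint pool
  n_cont <- 2L * (floor(config$contaminant_fraction * config$n_genes) %/% 2L)
  n_mod <- sum(config$planted_modules$n_genes)
  n_special <- n_cont + n_mod + config$gender_gene_count
  if (n_special > config$n_genes) stop("not enough genes for planted structure")
  roles <- with_stage_seed(config$seed, "roles", sample(genes, n_special))
  idx <- 0L
  take <- function(n) {
    out <- roles[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  cont_rpe <- take(n_cont %/% 2L)   # expressed in RPE-choroid only
  cont_ret <- take(n_cont %/% 2L)   # expressed in retina only
  module_genes <- lapply(seq_len(nrow(config$planted_modules)), function(i) {
    take(config$planted_modules$n_genes[i])
  })
  gender_genes <- take(config$gender_gene_count)

  meta <- with_stage_seed(config$seed, "donors", {
    data.frame(
      donor = sprintf("D%03d", seq_len(n_donor)),
      phenotype = classes,
      age = round(stats::runif(n_donor, config$age_range[1], config$age_range[2])),
      gender = sample(c("M", "F"), n_donor, replace = TRUE),
      cohort = "synthetic",
      stringsAsFactors = FALSE
    )
  })
  # guarantee both genders so the gender filter is applicable
  if (length(unique(meta$gender)) == 1 && n_donor >= 2) {
    meta$gender[1] <- setdiff(c("M", "F"), meta$gender[1])
  }

  samples <- expand.grid(donor = meta$donor, tissue = tissue_levels(),
                         region = region_levels(), stringsAsFactors = FALSE)
  samples <- merge(samples, meta, by = "donor", sort = FALSE)
  samples$sample_id <- paste(samples$donor,
                             ifelse(samples$tissue == "RPE-choroid", "RPE", "RET"),
                             ifelse(samples$region == "macula", "mac", "ext"),
                             sep = "_")
  samples <- samples[order(samples$tissue, samples$donor, samples$region), ]
  rownames(samples) <- NULL

  baseline <- with_stage_seed(config$seed, "baseline", {
    stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  })
  names(baseline) <- genes
  # Planted-module genes are placed on transcripts expressed above the
  # array detection floor (left-truncated baseline at mean - 1 sd): a
  # module planted on unmeasurable genes cannot be recovered by any method
  # and would only re-test the variance filter.
  mod_gene_all <- unlist(module_genes)
  if (length(mod_gene_all) > 0) {
    z <- (baseline[mod_gene_all] - config$baseline_mean) / config$baseline_sd
    lo <- stats::pnorm(-1)
    zt <- stats::qnorm(lo + stats::pnorm(z) * (1 - lo))
    baseline[mod_gene_all] <- config$baseline_mean + config$baseline_sd * zt
  }
  cont_own <- with_stage_seed(config$seed, "contaminant", {
    stats::rnorm(n_cont, config$contaminant_mean, config$contaminant_sd)
  })
  names(cont_own) <- c(cont_rpe, cont_ret)
  floor_log2 <- log2(config$contaminant_floor)

  gender_dir <- rep(c(1, -1), length.out = config$gender_gene_count) # +1 male-up
  names(gender_dir) <- gender_genes

  pm <- config$planted_modules
  truth_members <- if (nrow(pm) > 0) {
    do.call(rbind, lapply(seq_len(nrow(pm)), function(i) {
      data.frame(gene = module_genes[[i]],
                 phenotype = pm$phenotype[i], region = pm$region[i],
                 direction = pm$direction[i], effect = pm$effect[i],
                 tissue = pm$tissue[i],
                 module = paste(pm$tissue[i], pm$phenotype[i], pm$direction[i]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(), phenotype = character(), region = character(),
               direction = character(), effect = numeric(), tissue = character(),
               module = character(), stringsAsFactors = FALSE)
  }

  expr <- list()
  for (tis in tissue_levels()) {
    smp <- samples[samples$tissue == tis, ]
    mu <- matrix(baseline[probe_map$gene], nrow = config$n_probes,
                 ncol = nrow(smp))
    rownames(mu) <- probes
    colnames(mu) <- smp$sample_id

    own <- if (tis == "RPE-choroid") cont_rpe else cont_ret
    other <- if (tis == "RPE-choroid") cont_ret else cont_rpe
    mu[probe_map$gene %in% own, ] <- cont_own[probe_map$gene[probe_map$gene %in% own]]
    mu[probe_map$gene %in% other, ] <- floor_log2

    male <- smp$gender == "M"
    for (g in gender_genes) {
      rows <- probe_map$gene == g
      mu[rows, male] <- mu[rows, male] + gender_dir[g] * config$gender_effect / 2
      mu[rows, !male] <- mu[rows, !male] - gender_dir[g] * config$gender_effect / 2
    }

    if (nrow(pm) > 0) {
      for (i in seq_len(nrow(pm))) {
        if (pm$tissue[i] != tis) next
        # GA and CNV plantings also shift mixed GA-CNV donors: a mixed eye
        # carries both expression programs, which is why the analysis pools
        # them into both groups.
        in_pheno <- if (pm$phenotype[i] == "Global") {
          smp$phenotype != "Normal"
        } else if (pm$phenotype[i] == "MD") {
          smp$phenotype %in% c("MD1", "MD2")
        } else if (pm$phenotype[i] %in% c("GA", "CNV")) {
          smp$phenotype %in% c(pm$phenotype[i], "GA-CNV")
        } else smp$phenotype == pm$phenotype[i]
        in_region <- if (pm$region[i] == "both") rep(TRUE, nrow(smp))
                     else smp$region == pm$region[i]
        cols <- in_pheno & in_region
        rows <- probe_map$gene %in% module_genes[[i]]
        shift <- if (pm$direction[i] == "Up") pm$effect[i] else -pm$effect[i]
        mu[rows, cols] <- mu[rows, cols] + shift
      }
    }

    noise <- with_stage_seed(config$seed, paste0("noise_", tis), {
      matrix(stats::rnorm(length(mu), 0, config$noise_sd), nrow = nrow(mu))
    })
    expr[[tis]] <- net_intensity(2^(mu + noise))
  }

  truth <- structure(list(
    module_membership = truth_members,
    contaminants = list(`RPE-choroid` = cont_ret, retina = cont_rpe),
    expressed_only_in = list(`RPE-choroid` = cont_rpe, retina = cont_ret),
    gender_genes = gender_genes,
    effect_sizes = if (nrow(pm) > 0) {
      stats::setNames(pm$effect, paste(pm$tissue, pm$phenotype, pm$direction))
    } else numeric()
  ), class = "synthetic_truth")

  study <- expression_study(expr,
                            meta = samples[, c("sample_id", "donor", "tissue",
                                               "region", "phenotype", "age",
                                               "gender", "cohort")],
                            probe_map = probe_map)
  list(study = study, truth = truth)
}

#' Simulate an Erdos-Renyi background interaction graph
#'
#' Stand-in for a database-scale protein-association background: each node
#' pair is connected independently with probability
#' `mean_degree / (n_nodes - 1)`.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param mean_degree Expected node degree, in (0, n_nodes - 1).
#' @param seed Integer seed.
#' @param node_names Optional character vector of node names (defaults to
#'   `N0001`, ...).
#' @return An [interaction_graph()] with source tag `"synthetic"`, score 1.
#' @export
simulate_background_graph <- function(n_nodes, mean_degree, seed = 1L,
                                      node_names = NULL) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (mean_degree <= 0 || mean_degree >= n_nodes) {
    stop("mean_degree must be in (0, n_nodes - 1]")
  }
  if (is.null(node_names)) node_names <- sprintf("N%05d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  p <- min(1, mean_degree / (n_nodes - 1))
  el <- with_stage_seed(seed, "ergraph", {
    g <- igraph::sample_gnp(n_nodes, p, directed = FALSE, loops = FALSE)
    igraph::as_edgelist(g, names = FALSE)
  })
  edges <- data.frame(node1 = node_names[el[, 1]], node2 = node_names[el[, 2]],
                      score = 1, source = "synthetic",
                      stringsAsFactors = FALSE)
  interaction_graph(edges, nodes = node_names)
}

#' Densify a gene set inside a background graph
#'
#' Adds edges among the given genes independently with probability
#' `extra_density`, keeping all original edges; used to plant
#' connectivity-enriched modules for testing enrichment detection.
#'
#' @param graph An [interaction_graph()].
#' @param genes Character vector of node names, all present in `graph`.
#' @param extra_density Probability in [0, 1] for each within-set pair.
#' @param seed Integer seed.
#' @return The augmented [interaction_graph()].
#' @export
embed_module_edges <- function(graph, genes, extra_density, seed = 1L) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (extra_density < 0 || extra_density > 1) {
    stop("extra_density must be in [0, 1]")
  }
  missing <- setdiff(genes, graph$nodes)
  if (length(missing) > 0) {
    stop("gene(s) not in graph: ", paste(missing, collapse = ", "))
  }
  if (extra_density == 0 || length(genes) < 2) return(graph)
  pairs <- utils::combn(sort(genes), 2)
  keep <- with_stage_seed(seed, "embed", {
    stats::runif(ncol(pairs)) < extra_density
  })
  new_edges <- data.frame(node1 = pairs[1, keep], node2 = pairs[2, keep],
                          score = 1, source = "synthetic",
                          stringsAsFactors = FALSE)
  combined <- rbind(graph$edges, new_edges)
  key <- paste(pmin(combined$node1, combined$node2),
               pmax(combined$node1, combined$node2))
  interaction_graph(combined[!duplicated(key), ], nodes = graph$nodes)
}
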