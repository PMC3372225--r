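#' Expression study container
#'
#' Bundles per-tissue probe-by-sample expression matrices with sample
#' metadata and a probe-to-gene map, validating cross-references.
#'
#' @param expr Named list of numeric matrices (probes x samples), one per
#'   tissue; names from [tissue_levels()].
#' @param meta Data frame with columns `sample_id`, `donor`, `tissue`,
#'   `region`, `phenotype`, `age`, `gender`, `cohort`.
#' @param probe_map Data frame with columns `probe_id`, `gene`. Probes absent
#'   from the map are carried under their probe id downstream.
#' @return An `expression_study` object (list with the three components).
#' @export
expression_study <- function(expr, meta, probe_map = NULL) {
  stopifnot(is.list(expr), length(expr) >= 1, !is.null(names(expr)))
  bad_tissue <- setdiff(names(expr), tissue_levels())
  if (length(bad_tissue) > 0) {
    stop("unknown tissue(s): ", paste(bad_tissue, collapse = ", "),
         "; allowed: ", paste(tissue_levels(), collapse = ", "))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("sample_id", "donor", "tissue", "region", "phenotype", "age",
              "gender")
  miss <- setdiff(needed, names(meta))
  if (length(miss) > 0) stop("metadata missing column(s): ",
                             paste(miss, collapse = ", "))
  if (is.null(meta$cohort)) meta$cohort <- "unspecified"
  bad_ph <- setdiff(unique(meta$phenotype), phenotype_levels())
  if (length(bad_ph) > 0) {
    stop("unknown phenotype label(s): ", paste(bad_ph, collapse = ", "),
         "; allowed: ", paste(phenotype_levels(), collapse = ", "))
  }
  bad_rg <- setdiff(unique(meta$region), region_levels())
  if (length(bad_rg) > 0) stop("unknown region label(s): ",
                               paste(bad_rg, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  for (tis in names(expr)) {
    m <- expr[[tis]]
    stopifnot(is.matrix(m), is.numeric(m))
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("expression matrix for ", tis, " needs probe and sample names")
    }
    unknown <- setdiff(colnames(m), meta$sample_id)
    if (length(unknown) > 0) {
      stop("sample(s) in ", tis, " matrix missing from metadata: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!is.null(probe_map)) {
    probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
    stopifnot(all(c("probe_id", "gene") %in% names(probe_map)))
    if (anyDuplicated(probe_map$probe_id)) {
      stop("probe_map maps a probe to more than one gene")
    }
  }
  structure(list(expr = expr, meta = meta, probe_map = probe_map),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$expr), "tissue matrix/matrices\n")
  for (tis in names(x$expr)) {
    cat("  ", tis, ": ", nrow(x$expr[[tis]]), " probes x ",
        ncol(x$expr[[tis]]), " samples\n", sep = "")
  }
  cat("  phenotypes:",
      paste(sort(unique(x$meta$phenotype)), collapse = ", "), "\n")
  invisible(x)
}

#' Metadata rows for one tissue's samples, in matrix column order
#' @param study An [expression_study()].
#' @param tissue Tissue name.
#' @return Data frame of metadata aligned to `colnames(study$expr[[tissue]])`.
#' @export
sample_meta <- function(study, tissue) {
  stopifnot(inherits(study, "expression_study"), tissue %in% names(study$expr))
  m <- study$meta[match(colnames(study$expr[[tissue]]), study$meta$sample_id), ]
  rownames(m) <- NULL
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a study to a directory of TSV files
#'
#' Emits one `expr_<tissue>.tsv` per tissue (probes as rows, first column
#' `probe_id`), `metadata.tsv` and `probe_map.tsv`.
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tis in names(study$expr)) {
    m <- study$expr[[tis]]
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, paste0("expr_", gsub("[^A-Za-z0-9]", "_", tis),
                                        ".tsv")))
  }
  write_tsv(study$meta, file.path(dir, "metadata.tsv"))
  if (!is.null(study$probe_map)) {
    write_tsv(study$probe_map, file.path(dir, "probe_map.tsv"))
  }
  invisible(dir)
}

#' Load a study from TSV files
#'
#' @param expr_paths Named character vector of expression TSV paths, names
#'   being tissue labels.
#' @param meta_path Path to the metadata TSV.
#' @param mapping_path Optional path to the probe-to-gene TSV.
#' @return An [expression_study()]; cross-file consistency is enforced
#'   (unknown phenotype labels and samples missing from metadata are errors).
#' @export
load_study <- function(expr_paths, meta_path, mapping_path = NULL) {
  stopifnot(!is.null(names(expr_paths)))
  expr <- lapply(expr_paths, function(p) {
    df <- read_tsv(p)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  })
  meta <- read_tsv(meta_path)
  probe_map <- if (!is.null(mapping_path)) read_tsv(mapping_path) else NULL
  expression_study(expr, meta, probe_map)
}

#' Load a study directory written by [write_study()]
#' @param dir Directory path.
#' @return An [expression_study()].
#' @export
load_study_dir <- function(dir) {
  files <- list.files(dir, pattern = "^expr_.*\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no expr_*.tsv files in ", dir)
  names(files) <- vapply(sub("^expr_(.*)\\.tsv$", "\\1", basename(files)),
                         function(s) {
                           hit <- tissue_levels()[gsub("[^A-Za-z0-9]", "_",
                                                       tissue_levels()) == s]
                           if (length(hit) == 1) hit else s
                         }, character(1))
  mp <- file.path(dir, "probe_map.tsv")
  load_study(files, file.path(dir, "metadata.tsv"),
             if (file.exists(mp)) mp else NULL)
}
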