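#' Run the full enrichment pipeline on files
#'
#' Composes the whole analysis: read expression matrix, design and GMT,
#' quantile-normalize, compute per-gene fold change and pooled-t
#' significance, optionally collapse probes to genes, run the chosen
#' enrichment method(s), and write one ranked results TSV per method plus
#' a run log and a provenance echo of the configuration.
#'
#' @param expression_file tab-delimited expression matrix (header of sample
#'   names, first column row IDs, linear-scale intensities).
#' @param design_file two-column TSV (sample, class).
#' @param gmt_file gene-set collection in GMT format.
#' @param out_dir output directory, created if needed.
#' @param probe_map_file optional two-column TSV (probe, gene); when given,
#'   probe statistics are collapsed to gene level (mean fold change,
#'   minimum p) before enrichment.
#' @param method one of the four methods or `"all"` (default) to write one
#'   results file per method for side-by-side comparison.
#' @param a score power for the weighted methods (default 1).
#' @param alpha per-gene significance threshold (default 0.01).
#' @param top_k top-list cap echoed into the log (default 10).
#' @param case label of the case class in the design file (default
#'   `"case"`).
#' @return named character vector of written results paths, invisibly.
#' @export
run_enrichment <- function(expression_file, design_file, gmt_file, out_dir,
                           probe_map_file = NULL, method = "all", a = 1,
                           alpha = 0.01, top_k = 10L, case = "case") {
  methods <- c("hypergeometric", "chi2", "weighted_hypergeometric",
               "weighted_chi2")
  if (!identical(method, "all")) methods <- match.arg(method, methods)
  m <- read_expression_matrix(expression_file)
  design <- read_design(design_file)
  if (!setequal(names(design), colnames(m))) {
    stop("sample names in design and expression matrix disagree")
  }
  sets <- read_gmt(gmt_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  norm <- quantile_normalize(m)
  st <- gene_stats(norm, design, alpha = alpha, case = case)
  if (!is.null(probe_map_file)) {
    map <- read_probe_map(probe_map_file)
    st2 <- collapse_probes(
      data.frame(probe_id = st$gene_id, fold_change = st$fold_change,
                 p_value = st$p_value, stringsAsFactors = FALSE), map)
    st <- data.frame(gene_id = st2$gene_id, fold_change = st2$fold_change,
                     p_value = st2$p_value,
                     is_significant = st2$p_value < alpha,
                     stringsAsFactors = FALSE)
  }

  log_lines <- c(
    sprintf("genes on array (N): %d", nrow(st)),
    sprintf("significant genes at alpha=%g (m): %d",
            alpha, sum(st$p_value < alpha)),
    sprintf("pathways: %d", length(sets))
  )
  out <- character()
  for (meth in methods) {
    fit <- enrich(st, sets, method = meth, a = a, alpha = alpha)
    path <- file.path(out_dir, paste0("results_", meth, ".tsv"))
    write_enrichment(fit, path)
    out[meth] <- path
    log_lines <- c(log_lines,
                   sprintf("%s: %d untestable, %d degenerate; top-%d head: %s",
                           meth, fit$n_untestable, fit$n_degenerate, top_k,
                           paste(utils::head(fit$table$set_id, 3L),
                                 collapse = ", ")))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  writeLines(c(
    sprintf("expression_file=%s", expression_file),
    sprintf("design_file=%s", design_file),
    sprintf("gmt_file=%s", gmt_file),
    sprintf("probe_map_file=%s",
            if (is.null(probe_map_file)) "" else probe_map_file),
    sprintf("method=%s", paste(methods, collapse = ",")),
    sprintf("a=%g", a), sprintf("alpha=%g", alpha),
    sprintf("top_k=%d", top_k), sprintf("case=%s", case)
  ), file.path(out_dir, "config.txt"))
  invisible(out)
}

#' Cross-dataset consistency from results files
#'
#' Reads several per-dataset results TSVs (as written by
#' [run_enrichment()]), extracts each dataset's top-k pathway list and
#' tabulates the pathways recurring in at least `min_datasets` of them.
#'
#' @param result_files character vector (>= 2) of results TSV paths; names
#'   are used as dataset IDs (file base names otherwise).
#' @param out_file path of the recurrence TSV to write, or `NULL` to skip.
#' @param min_datasets recurrence threshold (default 2).
#' @param top_k top-list cap (default 10).
#' @param p_cutoff optional raw p-value filter applied before capping.
#' @return the recurrence data frame (see [cross_tabulate()]), invisibly
#'   when `out_file` is given.
#' @export
run_meta <- function(result_files, out_file = NULL, min_datasets = 2L,
                     top_k = 10L, p_cutoff = NULL) {
  if (length(result_files) < 2L) stop("need at least 2 result files")
  ids <- names(result_files)
  if (is.null(ids)) {
    ids <- tools::file_path_sans_ext(basename(result_files))
  }
  tops <- lapply(result_files, read_top_pathways, k = top_k,
                 p_cutoff = p_cutoff)
  names(tops) <- ids
  tab <- cross_tabulate(tops, min_datasets = min_datasets)
  if (!is.null(out_file)) {
    utils::write.table(tab, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
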