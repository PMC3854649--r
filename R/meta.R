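#' Tabulate pathways recurring across datasets
#'
#' Given the top-k pathway lists of several related datasets (one list per
#' dataset), reports every pathway present in at least `min_datasets`
#' lists, with the identity and number of datasets containing it. This is
#' the device used to compare the consistency of enrichment methods across
#' similar experiments: a method that keeps finding the same pathways in
#' independent datasets of the same condition is preferred over one whose
#' top lists barely overlap.
#'
#' @param top_lists named list of character vectors: dataset ID ->
#'   top-ranked set IDs (no duplicates within a list).
#' @param min_datasets minimum number of datasets a pathway must appear in
#'   (default 2).
#' @return data frame with columns `set_id`, `n_datasets`, `datasets`
#'   (comma-separated), sorted by count descending then set ID.
#' @export
cross_tabulate <- function(top_lists, min_datasets = 2L) {
  if (!is.list(top_lists) || length(top_lists) < 2L) {
    stop("need top lists from at least 2 datasets")
  }
  if (is.null(names(top_lists))) {
    names(top_lists) <- paste0("dataset", seq_along(top_lists))
  }
  if (any(vapply(top_lists, anyDuplicated, integer(1)) > 0L)) {
    stop("top lists must not contain duplicate pathways")
  }
  long <- data.frame(
    dataset = rep(names(top_lists), lengths(top_lists)),
    set_id = unlist(top_lists, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  counts <- tapply(long$dataset, long$set_id, function(d) sort(unique(d)))
  n <- lengths(counts)
  keep <- n >= min_datasets
  out <- data.frame(
    set_id = names(counts)[keep],
    n_datasets = as.integer(n[keep]),
    datasets = vapply(counts[keep], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$n_datasets, out$set_id), , drop = FALSE]
}

#' Consistency summary of top-k lists across datasets
#'
#' Quantifies cross-dataset agreement as the mean pairwise overlap
#' fraction `|A intersect B| / k` over all dataset pairs, plus the number
#' of pathways at each recurrence level (how many pathways appear in
#' exactly 1, 2, ... datasets).
#'
#' @param top_lists named list of character vectors of equal cap `k`.
#' @param k the list cap used; defaults to the longest list.
#' @return list with `mean_overlap`, `pairwise` (data frame of per-pair
#'   overlaps) and `recurrence` (table: recurrence level -> pathway count).
#' @export
consistency_score <- function(top_lists, k = NULL) {
  if (!is.list(top_lists) || length(top_lists) < 2L) {
    stop("need top lists from at least 2 datasets")
  }
  if (is.null(names(top_lists))) {
    names(top_lists) <- paste0("dataset", seq_along(top_lists))
  }
  if (is.null(k)) k <- max(lengths(top_lists))
  ids <- names(top_lists)
  pairs <- utils::combn(ids, 2L)
  ov <- apply(pairs, 2L, function(p) {
    length(intersect(top_lists[[p[1]]], top_lists[[p[2]]])) / k
  })
  counts <- table(table(unlist(top_lists, use.names = FALSE)))
  list(mean_overlap = mean(ov),
       pairwise = data.frame(a = pairs[1, ], b = pairs[2, ],
                             overlap = ov, stringsAsFactors = FALSE),
       recurrence = counts)
}

#' Read a results TSV back as a top-k pathway list
#'
#' Reads a table written by [write_enrichment()] and returns the IDs of the
#' `k` best-ranked pathways, optionally after a raw p-value cutoff.
#'
#' @param path results TSV path.
#' @param k list cap (default 10).
#' @param p_cutoff optional raw p-value filter applied before capping.
#' @return character vector of pathway IDs in rank order.
#' @export
read_top_pathways <- function(path, k = 10L, p_cutoff = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  tab <- tab[order(tab$rank), , drop = FALSE]
  if (!is.null(p_cutoff)) tab <- tab[tab$p_value < p_cutoff, , drop = FALSE]
  utils::head(tab$pathway_id, k)
}
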