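#' Construct a gene-set collection
#'
#' A gene-set collection is an ordered list of named gene sets (pathways),
#' each holding a unique identifier, a human-readable name and a vector of
#' unique member gene identifiers. Gene identifiers are opaque strings; the
#' package imposes no organism or nomenclature logic.
#'
#' @param members named list of character vectors; names are set identifiers,
#'   elements are member gene IDs. Duplicate members within a set are
#'   silently de-duplicated (set semantics).
#' @param set_names optional character vector of human-readable pathway
#'   names, parallel to `members`; defaults to the set identifiers.
#' @return an object of class `gene_set_collection`: a list with elements
#'   `ids`, `names` (named by id) and `members` (named list of character
#'   vectors).
#' @examples
#' gs <- gene_set_collection(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")))
#' length(gs)
#' @export
gene_set_collection <- function(members, set_names = NULL) {
  if (!is.list(members) || is.null(names(members)) ||
      any(!nzchar(names(members)))) {
    stop("'members' must be a named list of character vectors")
  }
  ids <- names(members)
  if (anyDuplicated(ids)) {
    stop("duplicate set identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0L)) {
    stop("gene sets must be non-empty: ",
         paste(ids[lengths(members) == 0L], collapse = ", "))
  }
  if (is.null(set_names)) set_names <- ids
  if (length(set_names) != length(ids)) {
    stop("'set_names' must be parallel to 'members'")
  }
  structure(
    list(ids = ids, names = stats::setNames(as.character(set_names), ids),
         members = stats::setNames(members, ids)),
    class = "gene_set_collection"
  )
}

#' @export
length.gene_set_collection <- function(x) length(x$ids)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$ids), "sets,",
      length(unique(unlist(x$members, use.names = FALSE))),
      "distinct genes\n")
  show <- utils::head(x$ids, 5L)
  for (id in show) {
    cat(sprintf("  %s (%d genes): %s\n", id, length(x$members[[id]]),
                paste(utils::head(x$members[[id]], 4L), collapse = ", ")))
  }
  if (length(x$ids) > 5L) cat("  ...\n")
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the standard tab-delimited gene-set format: one set per line,
#' fields are set name, description, then member gene IDs. The set name is
#' used as the set identifier and the description as the human-readable
#' pathway name (falling back to the identifier when empty).
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(ids = character(), names = character(),
                          members = stats::setNames(list(), character())),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L],
         ": expected at least 3 tab-separated fields, got ",
         length(fields[[bad[1L]]]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set name in GMT file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- vapply(fields, `[[`, character(1), 2L)
  descs <- ifelse(nzchar(descs), descs, ids)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(members) <- ids
  gene_set_collection(members, set_names = descs)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets a [gene_set_collection].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(sets$ids, function(id) {
    paste(c(id, sets$names[[id]], sets$members[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' The map is a headerless two-column tab-separated file (probe ID, gene
#' ID). A probe may map to at most one gene; many probes may map to the
#' same gene. Probe-to-many-gene mappings are rejected.
#'
#' @param path path to the two-column TSV.
#' @return a data frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  map <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("probe_id", "gene_id"),
                           quote = "", comment.char = "")
  if (anyDuplicated(map$probe_id)) {
    stop("probe mapped to more than one gene: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]),
               collapse = ", "))
  }
  map
}

#' Collapse probe-level statistics to gene level
#'
#' Multiple array probes can interrogate the same gene. Per gene, the fold
#' change is the arithmetic mean of its probes' linear-scale fold changes
#' and the p-value is the minimum over its probes. Probes absent from the
#' map are dropped with a message.
#'
#' @param probe_stats data frame with columns `probe_id`, `fold_change`
#'   (linear scale, > 0) and `p_value`.
#' @param map data frame with columns `probe_id`, `gene_id` (one gene per
#'   probe), as from [read_probe_map()].
#' @return a data frame with columns `gene_id`, `fold_change`, `p_value`,
#'   one row per mapped gene.
#' @export
collapse_probes <- function(probe_stats, map) {
  need <- c("probe_id", "fold_change", "p_value")
  if (!all(need %in% names(probe_stats))) {
    stop("'probe_stats' needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$probe_id)) {
    stop("probe mapped to more than one gene")
  }
  gene <- map$gene_id[match(probe_stats$probe_id, map$probe_id)]
  unmapped <- is.na(gene)
  if (all(unmapped)) stop("no probe in 'probe_stats' appears in the map")
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped probe(s) dropped")
  }
  ps <- probe_stats[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  fc <- tapply(ps$fold_change, gene, mean)
  pv <- tapply(ps$p_value, gene, min)
  out <- data.frame(gene_id = names(fc),
                    fold_change = as.numeric(fc),
                    p_value = as.numeric(pv[names(fc)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}
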