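# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation does not disturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic two-class expression study
#'
#' Describes a seeded synthetic dataset with known enrichment structure:
#' log-normal intensities for a binary case/control design, a collection
#' of non-overlapping random pathways, and selected "planted" pathways
#' whose member genes receive a class effect on the log2 scale. Three
#' effect modes mirror the situations the weighted tests are designed to
#' separate:
#'
#' \describe{
#'   \item{`significant_shift`}{all members shifted up by `magnitude` log2
#'     units with a tight within-group standard deviation (`within_sd`,
#'     default 0.5), so most members reach t-test significance — the
#'     regime classical ORA detects.}
#'   \item{`high_fc_nonsig`}{members shifted by `magnitude` with a large
#'     within-group standard deviation (`within_sd`, default 2.5), so the
#'     observed fold change is high but the t-test misses at alpha = 0.01 —
#'     the regime only score-weighted enrichment can see. Shift signs are
#'     random per gene.}
#'   \item{`bidirectional`}{members alternate between up- and down-shifts
#'     of `magnitude`, with background noise; the absolute-value gene score
#'     accumulates both directions.}
#' }
#'
#' @param n_genes number of genes on the array (default 500).
#' @param n_samples_per_class samples per class (default 5).
#' @param n_pathways number of gene sets (default 20).
#' @param pathway_size_range integer range of set sizes (default c(10, 25)).
#' @param planted list of planted effects; each element a list with
#'   `set_id` (one of `S1..Sn`), `mode` (above), `magnitude` (log2 shift,
#'   default 2) and optional `within_sd`.
#' @param noise_sd background within-group standard deviation on the log2
#'   scale (default 1).
#' @param base_log2 mean log2 intensity of a gene's baseline (default 8,
#'   i.e. intensities around 256), with gene baselines spread with sd 1.
#' @param seed RNG seed; the same spec always yields the identical dataset.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 500L, n_samples_per_class = 5L,
                            n_pathways = 20L,
                            pathway_size_range = c(10L, 25L),
                            planted = list(), noise_sd = 1,
                            base_log2 = 8, seed = 1L) {
  stopifnot(n_genes >= 1, n_samples_per_class >= 2, n_pathways >= 1,
            length(pathway_size_range) == 2L,
            pathway_size_range[1] <= pathway_size_range[2],
            noise_sd > 0, is.numeric(seed))
  if (pathway_size_range[2] * n_pathways > n_genes) {
    stop("pathway_size_range and n_pathways exceed n_genes ",
         "(pathways are sampled disjointly)")
  }
  modes <- c("significant_shift", "high_fc_nonsig", "bidirectional")
  planted <- lapply(planted, function(p) {
    if (is.null(p$set_id)) stop("planted effect missing field 'set_id'")
    if (is.null(p$mode) || !p$mode %in% modes) {
      stop("planted effect field 'mode' must be one of: ",
           paste(modes, collapse = ", "))
    }
    if (is.null(p$magnitude)) p$magnitude <- 2
    if (p$magnitude < 0) stop("planted effect field 'magnitude' must be >= 0")
    if (is.null(p$within_sd)) {
      p$within_sd <- switch(p$mode, high_fc_nonsig = 2.5,
                            significant_shift = 0.5, noise_sd)
    }
    p
  })
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 planted = planted, noise_sd = noise_sd,
                 base_log2 = base_log2, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a two-class expression dataset with known enrichment structure
#'
#' Draws gene baselines, builds disjoint random pathways, applies the
#' planted class effects on the log2 scale and returns linear-scale
#' intensities, so the output plugs directly into [quantile_normalize()]
#' and [gene_stats()]. Fixing the seed in the spec makes the output
#' bit-identical across calls.
#'
#' @param spec a [simulation_spec()].
#' @return a list with `expression` (linear intensity matrix, genes x
#'   samples), `design` (named class-label vector, values `"case"` /
#'   `"control"`), `sets` (a [gene_set_collection]) and `spec`.
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  planted_ids <- vapply(spec$planted, `[[`, character(1), "set_id")
  all_ids <- paste0("S", seq_len(spec$n_pathways))
  if (!all(planted_ids %in% all_ids)) {
    stop("planted set_id(s) outside the generated collection: ",
         paste(setdiff(planted_ids, all_ids), collapse = ", "))
  }
  with_seed(spec$seed, {
    n <- spec$n_genes
    ns <- spec$n_samples_per_class
    genes <- sprintf("g%04d", seq_len(n))
    samples <- c(paste0("case_", seq_len(ns)),
                 paste0("control_", seq_len(ns)))
    design <- stats::setNames(rep(c("case", "control"), each = ns), samples)

    # disjoint pathways over a shuffled gene order
    sizes <- sample(seq(spec$pathway_size_range[1],
                        spec$pathway_size_range[2]), spec$n_pathways,
                    replace = TRUE)
    pool <- sample(genes)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    members <- lapply(seq_len(spec$n_pathways),
                      function(i) sort(pool[starts[i]:stops[i]]))
    names(members) <- all_ids
    sets <- gene_set_collection(members)

    baseline <- stats::rnorm(n, spec$base_log2, 1)
    log2m <- matrix(stats::rnorm(n * 2L * ns, 0, spec$noise_sd), n, 2L * ns,
                    dimnames = list(genes, samples)) + baseline

    is_case <- design == "case"
    for (p in spec$planted) {
      idx <- match(sets$members[[p$set_id]], genes)
      shift <- switch(p$mode,
        significant_shift = rep(p$magnitude, length(idx)),
        high_fc_nonsig = p$magnitude * sample(c(-1, 1), length(idx),
                                              replace = TRUE),
        bidirectional = p$magnitude * rep_len(c(1, -1), length(idx)))
      if (p$within_sd != spec$noise_sd) {
        # re-draw planted genes' noise at the mode's own spread
        log2m[idx, ] <- baseline[idx] +
          matrix(stats::rnorm(length(idx) * 2L * ns, 0, p$within_sd),
                 length(idx), 2L * ns)
      }
      log2m[idx, is_case] <- log2m[idx, is_case] + shift
    }

    list(expression = 2^log2m, design = design, sets = sets, spec = spec)
  })
}

#' Write a simulated dataset to standard files
#'
#' Emits the expression TSV, design TSV and GMT consumed by the file-based
#' pipeline ([run_enrichment()]) and the command-line interface.
#'
#' @param dataset output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"sim"`).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    design = file.path(dir, paste0(prefix, "_design.tsv")),
    gmt = file.path(dir, paste0(prefix, "_sets.gmt"))
  )
  write_expression_matrix(dataset$expression, paths["expression"])
  utils::write.table(
    data.frame(sample = names(dataset$design),
               class = unname(dataset$design)),
    paths["design"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_gmt(dataset$sets, paths["gmt"])
  invisible(paths)
}
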