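#' Gene-set enrichment of per-gene differential-expression statistics
#'
#' Fits one of four over-representation tests to every pathway in a
#' collection, given per-gene fold changes and p-values:
#'
#' \describe{
#'   \item{`hypergeometric`}{classical ORA. With `N` genes on the array,
#'     `m` significant at `alpha`, `n` measured pathway members and `k` of
#'     them significant, the p-value is `P(X > k)` under
#'     Hypergeometric(N, m, n).}
#'   \item{`chi2`}{classical ORA through a 2x2 table (in/not in pathway
#'     vs. genes on array / significant genes; the significant column is
#'     exclusive, i.e. its second row is `m - k`), tested against the 1-df
#'     chi-squared upper tail.}
#'   \item{`weighted_hypergeometric`}{every gene carries a score
#'     `|log2 FC|^a` (see [gene_score()]). Per pathway, scores are rounded
#'     to whole numbers; `Q` is the rounded maximum member score and the
#'     pathway score `k` the sum of rounded member scores. A pseudo
#'     population is built in which each array gene is replicated `Q`
#'     times, the total rounded score over the array counts as successes
#'     (capped at the population size), and `n * Q` pseudo genes are drawn;
#'     the p-value is the hypergeometric tail beyond `k`. A gene's rounded
#'     score is the number of its pseudo-pathway copies counted
#'     significant, which makes the continuous weights compatible with the
#'     discrete distribution. When scores are the 0/1 significance
#'     indicator this reduces exactly to `hypergeometric`.}
#'   \item{`weighted_chi2`}{the 2x2 table with unrounded scores: the
#'     significant-genes column is replaced by the pathway score `k` (sum
#'     of member scores) and, in its second row, the remaining score mass
#'     on the array (`S - k`, with `S` the array-wide score sum). No
#'     discretization is needed because the chi-squared distribution is
#'     continuous.}
#' }
#'
#' Pathways whose measured-member count is zero are untestable; pathways
#' whose every member score rounds to zero (weighted hypergeometric with
#' `Q = 0`), or every array score is zero (weighted chi-squared with
#' `S = 0`), or with a zero table margin (chi-squared variants) are
#' degenerate. Both get p = 1 and are flagged in the `status` column rather
#' than dropped, so ranks remain a permutation of the whole collection.
#'
#' Results are ranked by p-value ascending, ties broken by larger pathway
#' score and then by set ID, so output is deterministic.
#'
#' @param stats data frame of per-gene statistics with columns `gene_id`,
#'   `fold_change` (linear scale, > 0) and `p_value`, one row per gene
#'   measured on the array — as produced by [gene_stats()] (optionally
#'   after [collapse_probes()]).
#' @param sets a [gene_set_collection].
#' @param method one of `"hypergeometric"`, `"chi2"`,
#'   `"weighted_hypergeometric"`, `"weighted_chi2"`.
#' @param a score exponent for the weighted methods (default 1).
#' @param alpha per-gene significance threshold for the unweighted methods
#'   (default 0.01).
#' @param score_margin for `weighted_chi2` only: `"exclusive"` (default)
#'   puts `S - k` in the not-in-pathway score cell, preserving the
#'   row-exclusive semantics of the unweighted table; `"total"` puts the
#'   whole array score sum `S` there, for sensitivity analysis.
#' @param gene_scores optional numeric vector of per-gene scores named by
#'   `gene_id`, overriding `|log2 FC|^a` in the weighted methods (expert
#'   use, e.g. to study the reduction to the unweighted test).
#' @return an object of class `enrichment`; see [print.enrichment()],
#'   [summary.enrichment()], [as.data.frame.enrichment()],
#'   [top_pathways()].
#' @examples
#' stats <- data.frame(gene_id = paste0("g", 1:20),
#'                     fold_change = c(rep(4, 5), rep(1.05, 15)),
#'                     p_value = c(rep(0.2, 5), rep(0.6, 15)))
#' sets <- gene_set_collection(list(up = paste0("g", 1:5),
#'                                  null = paste0("g", 11:18)))
#' enrich(stats, sets, method = "weighted_hypergeometric")
#' @export
enrich <- function(stats, sets,
                   method = c("hypergeometric", "chi2",
                              "weighted_hypergeometric", "weighted_chi2"),
                   a = 1, alpha = 0.01,
                   score_margin = c("exclusive", "total"),
                   gene_scores = NULL) {
  method <- match.arg(method)
  score_margin <- match.arg(score_margin)
  need <- c("gene_id", "fold_change", "p_value")
  if (!is.data.frame(stats) || !all(need %in% names(stats))) {
    stop("'stats' needs columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(stats$gene_id)) {
    stop("duplicate gene_id in 'stats'; collapse probes first")
  }
  stopifnot(inherits(sets, "gene_set_collection"))
  if (length(sets) == 0L) stop("empty gene-set collection")
  if (!(0 < alpha && alpha < 1)) stop("'alpha' must be in (0, 1)")

  N <- nrow(stats)
  sig <- stats$p_value < alpha
  m <- sum(sig)
  weighted <- method %in% c("weighted_hypergeometric", "weighted_chi2")

  if (weighted) {
    if (is.null(gene_scores)) {
      g_all <- stats::setNames(gene_score(stats$fold_change, a),
                               stats$gene_id)
    } else {
      if (is.null(names(gene_scores)) ||
          !all(stats$gene_id %in% names(gene_scores))) {
        stop("'gene_scores' must be named and cover every gene in 'stats'")
      }
      g_all <- gene_scores[stats$gene_id]
    }
    S <- sum(g_all)
    g_all_disc <- round_half_up(g_all)
    S_disc <- sum(g_all_disc)
  } else {
    g_all <- NULL; S <- NA_real_; S_disc <- NA_real_
  }

  one <- function(id) {
    members <- sets$members[[id]]
    idx <- match(members, stats$gene_id)
    idx <- idx[!is.na(idx)]
    n <- length(idx)
    if (n == 0L) {
      return(list(n = 0L, score = 0, p = 1, status = "untestable"))
    }
    switch(method,
      hypergeometric = {
        k <- sum(sig[idx])
        list(n = n, score = k,
             p = hypergeom_tail(N, m, n, k), status = "ok")
      },
      chi2 = {
        k <- sum(sig[idx])
        tab <- c(n11 = n, n12 = k, n21 = N - n, n22 = m - k)
        if (any(c(tab["n11"] + tab["n12"], tab["n21"] + tab["n22"],
                  tab["n11"] + tab["n21"], tab["n12"] + tab["n22"]) == 0)) {
          return(list(n = n, score = k, p = 1, status = "degenerate"))
        }
        ct <- chi2_statistic(tab[1], tab[2], tab[3], tab[4])
        list(n = n, score = k, p = ct$p_value, status = "ok")
      },
      weighted_hypergeometric = {
        g <- g_all_disc[idx]
        k <- sum(g)
        Q <- max(g)
        if (Q == 0) {
          return(list(n = n, score = k, p = 1, status = "degenerate"))
        }
        pop <- N * Q
        succ <- min(S_disc, pop)
        list(n = n, score = k,
             p = hypergeom_tail(pop, succ, n * Q, min(k, n * Q)),
             status = if (S_disc > pop) "successes_capped" else "ok")
      },
      weighted_chi2 = {
        k <- sum(g_all[idx])
        if (S == 0) {
          return(list(n = n, score = k, p = 1, status = "degenerate"))
        }
        n22 <- if (score_margin == "exclusive") S - k else S
        tab <- c(n, k, N - n, n22)
        if (any(c(tab[1] + tab[2], tab[3] + tab[4],
                  tab[1] + tab[3], tab[2] + tab[4]) == 0)) {
          return(list(n = n, score = k, p = 1, status = "degenerate"))
        }
        ct <- chi2_statistic(tab[1], tab[2], tab[3], tab[4])
        list(n = n, score = k, p = ct$p_value, status = "ok")
      })
  }

  rows <- lapply(sets$ids, one)
  tab <- data.frame(
    set_id = sets$ids,
    name = unname(sets$names[sets$ids]),
    n_genes = vapply(rows, function(r) as.integer(r$n), integer(1)),
    pathway_score = vapply(rows, function(r) as.numeric(r$score), numeric(1)),
    p_value = vapply(rows, function(r) r$p, numeric(1)),
    status = vapply(rows, function(r) r$status, character(1)),
    stringsAsFactors = FALSE
  )
  tab$fdr <- bh_fdr(tab$p_value)
  ord <- order(tab$p_value, -tab$pathway_score, tab$set_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab <- tab[, c("set_id", "name", "n_genes", "pathway_score",
                 "p_value", "fdr", "rank", "status")]

  structure(list(table = tab, method = method, a = a, alpha = alpha,
                 N = N, m = m, S = S, S_discrete = S_disc,
                 n_sets = length(sets),
                 n_untestable = sum(tab$status == "untestable"),
                 n_degenerate = sum(tab$status == "degenerate"),
                 call = match.call()),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, n = 10L, ...) {
  cat("Gene-set enrichment (", x$method, ")\n", sep = "")
  cat(sprintf("  array: %d genes, %d significant (alpha = %g)",
              x$N, x$m, x$alpha))
  if (x$method %in% c("weighted_hypergeometric", "weighted_chi2")) {
    cat(sprintf("; score power a = %g, array score sum S = %.4f", x$a, x$S))
  }
  cat("\n")
  cat(sprintf("  %d pathways tested (%d untestable, %d degenerate)\n",
              x$n_sets, x$n_untestable, x$n_degenerate))
  cat("Top pathways:\n")
  top <- utils::head(x$table, n)
  top$p_value <- signif(top$p_value, 4)
  top$fdr <- signif(top$fdr, 4)
  top$pathway_score <- signif(top$pathway_score, 6)
  print(top[, c("rank", "set_id", "name", "n_genes", "pathway_score",
                "p_value", "fdr")], row.names = FALSE)
  invisible(x)
}

#' Summarize an enrichment fit
#'
#' @param object an `enrichment` object.
#' @param p_cutoff pathways with raw p below this are counted as
#'   significant (default 0.05).
#' @param ... unused.
#' @return a list with the counts and the full result table, printed
#'   compactly.
#' @export
summary.enrichment <- function(object, p_cutoff = 0.05, ...) {
  out <- list(method = object$method,
              N = object$N, m = object$m,
              n_sets = object$n_sets,
              n_significant = sum(object$table$p_value < p_cutoff &
                                    object$table$status != "untestable"),
              p_cutoff = p_cutoff,
              n_untestable = object$n_untestable,
              n_degenerate = object$n_degenerate,
              table = object$table)
  class(out) <- "summary.enrichment"
  out
}

#' @export
print.summary.enrichment <- function(x, ...) {
  cat("Enrichment summary (", x$method, ")\n", sep = "")
  cat(sprintf("  %d pathways; %d with p < %g; %d untestable; %d degenerate\n",
              x$n_sets, x$n_significant, x$p_cutoff, x$n_untestable,
              x$n_degenerate))
  invisible(x)
}

#' @export
as.data.frame.enrichment <- function(x, ...) x$table

#' Bar plot of the strongest enrichments
#'
#' Horizontal bars of `-log10(p)` for the top-ranked pathways.
#'
#' @param x an `enrichment` object.
#' @param n number of pathways to show (default 10).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.enrichment <- function(x, n = 10L, ...) {
  top <- utils::head(x$table, n)
  top <- top[rev(seq_len(nrow(top))), ]
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(-log10(pmax(top$p_value, 1e-300)),
                    names.arg = substr(top$name, 1, 40), horiz = TRUE,
                    las = 1, cex.names = 0.7,
                    xlab = expression(-log[10](p)),
                    main = paste("Top pathways:", x$method), ...)
  invisible(x)
}

#' Top-ranked pathways from an enrichment fit
#'
#' Applies an optional raw p-value cutoff, then caps the list at the `k`
#' best-ranked pathways (ranking is p ascending with deterministic
#' tie-breaking by score and set ID).
#'
#' @param x an `enrichment` object.
#' @param k list cap (default 10).
#' @param p_cutoff optional raw p-value filter applied before capping.
#' @return the corresponding rows of the result table.
#' @export
top_pathways <- function(x, k = 10L, p_cutoff = NULL) {
  stopifnot(inherits(x, "enrichment"))
  tab <- x$table
  if (!is.null(p_cutoff)) tab <- tab[tab$p_value < p_cutoff, , drop = FALSE]
  utils::head(tab, k)
}

#' Write an enrichment result table as TSV
#'
#' Columns: `pathway_id`, `pathway_name`, `p_value`, `fdr`,
#' `pathway_score`, `n_genes`, `rank`, `status`.
#'
#' @param x an `enrichment` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "enrichment"))
  tab <- x$table
  out <- data.frame(pathway_id = tab$set_id, pathway_name = tab$name,
                    p_value = tab$p_value, fdr = tab$fdr,
                    pathway_score = tab$pathway_score,
                    n_genes = tab$n_genes, rank = tab$rank,
                    status = tab$status, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
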