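# Round half away from zero ("nearest whole number"); scores are
# non-negative so this is floor(x + 0.5), unlike base round()'s
# round-half-to-even.
round_half_up <- function(x) floor(x + 0.5)

#' Gene score from fold change
#'
#' The weight a gene carries in the weighted enrichment tests:
#' `|log2(fold_change)| ^ a`. The power `a` tunes how strongly expression
#' change drives enrichment; `a = 1` uses the absolute log2 fold change
#' directly, larger `a` emphasises extreme genes, and `a = 0` reduces every
#' changed gene to weight 1. Direction of change is ignored, so pathways
#' with both up- and down-regulated members still accumulate score.
#'
#' With `a = 0` an unchanged gene (fold change exactly 1) is scored 0, not
#' 1: `0^0` is taken as 0 here so that null genes never contribute.
#'
#' @param fold_change positive linear-scale fold change(s).
#' @param a non-negative exponent (default 1).
#' @return non-negative numeric score(s).
#' @examples
#' gene_score(7.793774)        # ~2.9623
#' gene_score(0.5, a = 2)      # 1
#' @export
gene_score <- function(fold_change, a = 1) {
  if (any(!is.finite(fold_change)) || any(fold_change <= 0)) {
    stop("'fold_change' must be positive and finite")
  }
  if (!is.numeric(a) || length(a) != 1L || a < 0) {
    stop("'a' must be a single non-negative number")
  }
  base <- abs(log2(fold_change))
  out <- base^a
  if (a == 0) out[base == 0] <- 0
  out
}

#' Score a pathway against per-gene statistics
#'
#' Restricts the set to the genes measured on the array, assigns each
#' member its gene score, and aggregates: the pathway score `k` is the sum
#' of member scores and `Q` is the maximum member score. For the discrete
#' (hypergeometric) variant, per-gene scores are rounded to the nearest
#' whole number before summing (`k_discrete`), and `Q_discrete` is `Q`
#' rounded.
#'
#' @param members character vector of member gene IDs, or a single set from
#'   a [gene_set_collection].
#' @param stats data frame with columns `gene_id`, `fold_change` (and
#'   optionally `p_value`), defining the array universe.
#' @param a score exponent, see [gene_score()].
#' @return a list with `n` (members measured on the array), `gene_scores`
#'   (named), `k`, `Q`, `k_discrete`, `Q_discrete`, and `untestable`
#'   (TRUE when no member is measured).
#' @export
score_pathway <- function(members, stats, a = 1) {
  members <- unique(as.character(members))
  idx <- match(members, stats$gene_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    return(list(n = 0L, gene_scores = stats::setNames(numeric(), character()),
                k = 0, Q = 0, k_discrete = 0L, Q_discrete = 0L,
                untestable = TRUE))
  }
  g <- gene_score(stats$fold_change[idx], a)
  names(g) <- stats$gene_id[idx]
  list(n = length(idx),
       gene_scores = g,
       k = sum(g),
       Q = max(g),
       k_discrete = as.integer(sum(round_half_up(g))),
       Q_discrete = as.integer(round_half_up(max(g))),
       untestable = FALSE)
}

# Array-wide context shared by all pathways of one analysis: N genes on
# the array, m significant at alpha, S the sum of all gene scores and its
# rounded-per-gene counterpart.
array_context <- function(stats, a = 1, alpha = 0.01) {
  sig <- if ("is_significant" %in% names(stats)) stats$is_significant
         else stats$p_value < alpha
  g <- gene_score(stats$fold_change, a)
  list(N = nrow(stats),
       m = sum(sig),
       significant = stats::setNames(sig, stats$gene_id),
       S = sum(g),
       S_discrete = as.integer(sum(round_half_up(g))))
}
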