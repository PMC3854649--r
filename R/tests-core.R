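#' Upper tail of the hypergeometric distribution
#'
#' `P(X > k)` for `X` ~ Hypergeometric(population `N`, successes `m`,
#' draws `n`): the probability of drawing strictly more than `k` successes.
#' Note the strict inequality — the observed count itself is excluded from
#' the tail. Evaluated through [stats::phyper()], which works in log space
#' and is stable for large arguments.
#'
#' @param N population size (genes on the array).
#' @param m number of successes in the population (significant genes).
#' @param n number of draws (genes in the pathway).
#' @param k observed success count; tail is beyond `k`.
#' @return probability in \[0, 1\].
#' @examples
#' hypergeom_tail(N = 10, m = 5, n = 4, k = 2)  # 55/210
#' @export
hypergeom_tail <- function(N, m, n, k) {
  if (any(c(N, m, n, k) < 0) || m > N || n > N || k > min(m, n)) {
    stop("require 0 <= m <= N, 0 <= n <= N, 0 <= k <= min(m, n)")
  }
  stats::phyper(k, m, N - m, n, lower.tail = FALSE)
}

#' Chi-squared statistic of a 2x2 enrichment table
#'
#' The uncorrected (no continuity correction) chi-squared statistic
#' `N (n11 n22 - n12 n21)^2 / (N1r N2r N1c N2c)` where the margins are the
#' row sums `N1r = n11 + n12`, `N2r = n21 + n22`, column sums
#' `N1c = n11 + n21`, `N2c = n12 + n22`, and `N` is the grand total. The
#' degrees of freedom of an r x c table are `(r - 1)(c - 1)`, hence 1 for
#' any 2x2 table. Cells may be non-integer: the weighted variant fills the
#' table with continuous pathway scores.
#'
#' @param n11,n12,n21,n22 non-negative cell values (row 1 = in pathway,
#'   row 2 = not in pathway; column 1 = genes on array, column 2 =
#'   significant genes or score).
#' @return list with `statistic`, `df` (always 1) and `p_value`, the upper
#'   tail of the 1-df chi-squared distribution.
#' @examples
#' chi2_statistic(50, 10, 950, 90)$statistic  # ~4.407
#' @export
chi2_statistic <- function(n11, n12, n21, n22) {
  cells <- as.numeric(c(n11, n12, n21, n22))  # doubles: margin products
  if (any(!is.finite(cells)) || any(cells < 0)) {  # overflow 32-bit ints
    stop("cells must be non-negative and finite")
  }
  n11 <- cells[1]; n12 <- cells[2]; n21 <- cells[3]; n22 <- cells[4]
  N1r <- n11 + n12; N2r <- n21 + n22
  N1c <- n11 + n21; N2c <- n12 + n22
  if (any(c(N1r, N2r, N1c, N2c) == 0)) {
    stop("chi-squared statistic undefined: zero margin")
  }
  N <- n11 + n12 + n21 + n22
  stat <- N * (n11 * n22 - n12 * n21)^2 / (N1r * N2r * N1c * N2c)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `adj_i = min_{j >= i} (p_j * M / j)` capped at 1, returned in
#' the original order. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
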