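#' Read a tab-delimited expression matrix
#'
#' Expected layout: a header row of sample names, first column of row
#' identifiers (probes or genes), remaining columns linear-scale
#' intensities. Missing or non-finite values are an error.
#'
#' @param path path to the TSV.
#' @return a numeric matrix, rows named by the first column.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "",
                          comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    stop("expression matrix contains missing or non-finite values")
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample design file
#'
#' Headerless TSV: sample name, class label. Exactly two classes are
#' required.
#'
#' @param path path to the design TSV.
#' @return named character vector mapping sample name to class label.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character",
                          col.names = c("sample", "class"),
                          quote = "", comment.char = "")
  stats::setNames(df$class, df$sample)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical intensity
#' distribution: each column's sorted values are replaced by the vector of
#' row means of the column-sorted matrix, and tied values within a column
#' receive the mean of the reference values they span. Delegates to
#' [limma::normalizeQuantiles()], the standard microarray implementation of
#' this convention.
#'
#' @param m numeric matrix, probes/genes in rows, samples in columns.
#' @return a matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("expression values must be finite numerics")
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-gene fold change and significance for a binary design
#'
#' For each row, computes the linear-scale fold change
#' `mean(case) / mean(control)` and a two-tailed pooled-variance (Student)
#' two-sample t-test p-value, then flags significance at `alpha`. Input is
#' expected to be quantile-normalized linear intensities.
#'
#' Degenerate rows where both groups have zero variance get p = 1 when the
#' means are equal and p = 0 otherwise. A non-positive control mean leaves
#' the fold change undefined and is an error.
#'
#' @param m numeric matrix of linear-scale intensities, rows are genes or
#'   probes, columns are samples.
#' @param design character vector of class labels named by sample
#'   (matching `colnames(m)`), or unnamed and parallel to the columns.
#'   Exactly two classes, each with at least two samples.
#' @param alpha significance threshold for the `is_significant` flag
#'   (default 0.01).
#' @param case label of the case class. Defaults to `"case"` when that
#'   label is present, otherwise it must be given explicitly.
#' @return data frame with columns `gene_id`, `fold_change`, `p_value`,
#'   `is_significant`.
#' @export
gene_stats <- function(m, design, alpha = 0.01, case = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (!is.null(names(design))) {
    if (!setequal(names(design), colnames(m))) {
      stop("design sample names do not match matrix columns")
    }
    design <- design[colnames(m)]
  } else if (length(design) != ncol(m)) {
    stop("unnamed design must have one label per column")
  }
  design <- as.character(design)
  classes <- unique(design)
  if (length(classes) != 2L) stop("design must have exactly two classes")
  if (is.null(case)) {
    if ("case" %in% classes) case <- "case" else
      stop("ambiguous class labels; name the case class via 'case='")
  }
  if (!case %in% classes) stop("case label '", case, "' not in design")
  is_case <- design == case
  if (sum(is_case) < 2L || sum(!is_case) < 2L) {
    stop("each class needs at least two samples")
  }
  if (!(0 < alpha && alpha < 1)) stop("'alpha' must be in (0, 1)")

  x <- m[, is_case, drop = FALSE]
  y <- m[, !is_case, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  if (any(m2 <= 0)) {
    stop("non-positive control mean for row(s): ",
         paste(utils::head(rownames(m)[m2 <= 0], 5L), collapse = ", "),
         " (fold change undefined)")
  }
  ss1 <- rowSums((x - m1)^2)
  ss2 <- rowSums((y - m2)^2)
  df <- n1 + n2 - 2L
  se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  zero_se <- se == 0
  p[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 1, 0)
  data.frame(gene_id = rownames(m),
             fold_change = m1 / m2,
             p_value = p,
             is_significant = p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
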