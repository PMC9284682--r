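#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median, over genes with a
#' positive geometric mean (i.e. no zero count anywhere), of the ratio of the
#' sample's count to the gene's geometric mean across samples. This is the
#' median-of-ratios step of the standard RNA-seq normalization.
#'
#' @param counts a [count_matrix()].
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' cm <- count_matrix(matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' size_factors(cm)  # c(s1 = 1/sqrt(2), s2 = sqrt(2))
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  all_pos <- rowSums(m == 0) == 0
  if (!any(all_pos))
    stop("size_factors: no gene has all-positive counts; ",
         "pseudo-reference fallback is disabled")
  lg <- log(m[all_pos, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - loggeo)))
  if (any(!is.finite(sf) | sf <= 0))
    stop("size_factors: non-finite or non-positive size factor")
  sf
}

#' Size-factor + log2 normalization
#'
#' Computes `log2(count / size_factor + pseudocount)` per entry. This is the
#' package's normalized-expression transform (a light-weight stand-in for
#' regularized-log transforms: same depth correction, no shrinkage).
#'
#' @param counts a [count_matrix()].
#' @param pseudocount positive real added inside the log (default 1).
#' @return an object of class `normalized_matrix`: list with `values`
#'   (genes x samples), `gene_ids`, `sample_ids`, `size_factors`,
#'   `pseudocount`.
#' @export
log_normalize <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"), pseudocount > 0)
  sf <- size_factors(counts)
  values <- log2(sweep(counts$counts, 2, sf, "/") + pseudocount)
  structure(list(values = values, gene_ids = counts$gene_ids,
                 sample_ids = counts$sample_ids, size_factors = sf,
                 pseudocount = pseudocount),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (pseudocount", x$pseudocount, ")\n")
  invisible(x)
}

#' Rank-based two-group differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test on normalized values between
#' the two groups, with Benjamini-Hochberg adjustment across all tested
#' genes. This is a distribution-free substitute for a negative-binomial GLM
#' test: it is used here only to count differentially expressed genes as a
#' soft indicator of correction quality, and its DEG counts are not
#' comparable to counts from model-based pipelines. Genes with zero variance
#' across all samples get p = 1. The test is exact for small tie-free groups
#' and uses the normal approximation with tie correction otherwise.
#'
#' @param norm a `normalized_matrix`, or a plain genes x samples numeric
#'   matrix with dimnames (e.g. confounder-corrected values).
#' @param table a [sample_table()] covering the matrix's samples.
#' @param group_a,group_b the two group labels to contrast (log2 fold change
#'   is mean(`group_a`) - mean(`group_b`)).
#' @param alpha adjusted p-value cutoff for the DEG count (default 0.05).
#' @return an object of class `de_result`: data.frame `table` (gene, log2fc,
#'   p_value, p_adjusted), `deg_count`, `alpha`.
#' @export
differential_expression <- function(norm, table, group_a, group_b,
                                    alpha = 0.05) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values
            else as.matrix(norm)
  stopifnot(inherits(table, "sample_table"), alpha > 0, alpha < 1)
  tab <- table[match(colnames(values), table$sample_id), , drop = FALSE]
  if (any(is.na(tab$sample_id)))
    stop("differential_expression: matrix samples missing from table")
  in_a <- tab$group == group_a
  in_b <- tab$group == group_b
  if (sum(in_a) < 2 || sum(in_b) < 2)
    stop("differential_expression: both groups need at least 2 samples ",
         "(", group_a, ": ", sum(in_a), ", ", group_b, ": ", sum(in_b), ")")
  a <- values[, in_a, drop = FALSE]
  b <- values[, in_b, drop = FALSE]
  pvals <- vapply(seq_len(nrow(values)), function(g) {
    x <- a[g, ]; y <- b[g, ]
    if (stats::var(c(x, y)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
  }, numeric(1))
  lfc <- rowMeans(a) - rowMeans(b)
  padj <- stats::p.adjust(pvals, method = "BH")
  res <- data.frame(gene = rownames(values), log2fc = lfc, p_value = pvals,
                    p_adjusted = padj, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = res, deg_count = sum(padj < alpha), alpha = alpha),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x$table), "genes tested,", x$deg_count,
      "DEGs at adjusted p <", x$alpha, "\n")
  invisible(x)
}
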