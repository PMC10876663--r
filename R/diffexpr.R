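#' Differential expression between two sample groups
#'
#' A lightweight two-group statistic: `log2fc = log2((mean(group1) +
#' pseudocount) / (mean(group2) + pseudocount))` on the linear scale, a
#' Welch t-test on `log2(expr + pseudocount)` per gene, and BH adjustment
#' across genes. Genes constant in both groups with equal means get p = 1
#' (never NaN); zero-variance genes with unequal means get p = 0.
#'
#' @param expr non-negative expression matrix, genes x samples, with
#'   rownames/colnames.
#' @param groups named character vector of group labels per sample.
#' @param group1,group2 labels of the two groups to contrast (fold change is
#'   group1 over group2; defaults `"tumor"` vs `"normal"`).
#' @param pseudocount added before ratios and logs (default 1).
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `mean_1`,
#'   `mean_2`, `p_value`, `q_value`, sorted by descending `log2fc` (ties by
#'   gene id) -- i.e. already in ranking order for [ranked_genes()].
#' @export
differential_expression <- function(expr, groups, group1 = "tumor",
                                    group2 = "normal", pseudocount = 1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (any(expr < 0, na.rm = TRUE))
    stop("differential_expression: expression must be >= 0")
  groups <- groups[colnames(expr)]
  i1 <- which(groups == group1)
  i2 <- which(groups == group2)
  if (length(i1) < 2 || length(i2) < 2)
    stop("differential_expression: need >= 2 samples per group")
  lg <- log2(expr + pseudocount)
  w <- welch_rows(lg, i1, i2)
  m1 <- rowMeans(expr[, i1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(expr[, i2, drop = FALSE], na.rm = TRUE)
  log2fc <- log2((m1 + pseudocount) / (m2 + pseudocount))
  q <- stats::p.adjust(w$p, method = "BH")
  out <- data.frame(gene_id = rownames(expr), log2fc = log2fc,
                    mean_1 = m1, mean_2 = m2,
                    p_value = w$p, q_value = q, stringsAsFactors = FALSE)
  o <- order(-out$log2fc, out$gene_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ranking metric from a differential-expression table
#'
#' @param de a `data.frame` from [differential_expression()].
#' @return A [ranked_genes()] object ranked by log2 fold change.
#' @export
de_ranking <- function(de) {
  ranked_genes(de$gene_id, de$log2fc)
}
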