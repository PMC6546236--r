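# Differential-expression stand-in and hypergeometric enrichment of DEGs
# among edited genes.

#' Simple differential-expression caller (Welch t + BH + fold change)
#'
#' A deliberately transparent stand-in for a full DE engine: per gene, a
#' Welch t-test on log2(expression + 1) between the two lines' replicates,
#' Benjamini-Hochberg correction across genes, and a DEG call iff the
#' adjusted p-value is at most `alpha` and |log2 fold change| is at least
#' log2(`fc_threshold`).  An externally produced DEG list can be used
#' anywhere a DEG set is accepted.
#'
#' @param expr Non-negative expression matrix, genes x samples, with column
#'   names of the form `line<i>_rep<j>` (or supply `sample_map`).
#' @param line_a,line_b The two cell-line labels to compare (e.g.
#'   `"line1"`).
#' @param sample_map Optional `data.frame` with `sample`, `line` columns
#'   overriding the column-name convention.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return `data.frame` per gene: `gene_id`, `log2fc` (line_b - line_a),
#'   `p`, `padj`, `deg`; the DEG gene-id set is in attribute `deg_set`.
#' @export
simple_deg <- function(expr, line_a, line_b, sample_map = NULL,
                       fc_threshold = 2, alpha = 0.05) {
  if (is.null(sample_map)) {
    sample_map <- data.frame(sample = colnames(expr),
                             line = sub("_rep\\d+$", "", colnames(expr)),
                             stringsAsFactors = FALSE)
  }
  cols_a <- sample_map$sample[sample_map$line == line_a]
  cols_b <- sample_map$sample[sample_map$line == line_b]
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stopf("simple_deg: need >= 2 replicates per line (got %d and %d)",
          length(cols_a), length(cols_b))
  la <- log2(expr[, cols_a, drop = FALSE] + 1)
  lb <- log2(expr[, cols_b, drop = FALSE] + 1)
  res <- data.frame(gene_id = rownames(expr),
                    log2fc = rowMeans(lb) - rowMeans(la),
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expr))) {
    a <- la[i, ]; b <- lb[i, ]
    res$p[i] <- if (stats::sd(c(a, b)) == 0) 1 else
      tryCatch(t.test(b, a)$p.value, error = function(e) 1)
  }
  res$padj <- p.adjust(res$p, method = "BH")
  res$deg <- res$padj <= alpha & abs(res$log2fc) >= log2(fc_threshold)
  attr(res, "deg_set") <- res$gene_id[res$deg]
  res
}

#' Hypergeometric enrichment of DEGs among edited genes
#'
#' Upper-tail hypergeometric test: with a universe of `N` genes of which
#' `K` are differentially expressed, and `n` edited genes of which `k` are
#' DEGs, the p-value is `P(X >= k)` for `X ~ Hypergeom(N, K, n)`:
#' `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.
#'
#' @param universe Character vector of all genes considered.
#' @param deg_set DEG gene ids (subset of `universe`).
#' @param edited_set Edited gene ids (subset of `universe`).
#' @return An `enrichment_result`: list with `N`, `K`, `n`, `k`, `p_value`
#'   and `fold_enrichment` = (k/n)/(K/N).
#' @export
hypergeom_enrichment <- function(universe, deg_set, edited_set) {
  universe <- unique(universe)
  deg_set <- unique(deg_set); edited_set <- unique(edited_set)
  if (!all(deg_set %in% universe))
    stopf("hypergeom_enrichment: DEG set not a subset of the universe")
  if (!all(edited_set %in% universe))
    stopf("hypergeom_enrichment: edited set not a subset of the universe")
  N <- length(universe); K <- length(deg_set); n <- length(edited_set)
  if (n == 0L) stopf("hypergeom_enrichment: no edited genes")
  k <- length(intersect(deg_set, edited_set))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K > 0L) (k / n) / (K / N) else NA_real_
  structure(list(N = N, K = K, n = n, k = k, p_value = p,
                 fold_enrichment = fold),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<enrichment_result> universe %d, DEGs %d, edited %d, edited DEGs %d\n",
    "  P(X >= k) = %.4g, fold enrichment = %.3g\n"),
    x$N, x$K, x$n, x$k, x$p_value, x$fold_enrichment))
  invisible(x)
}
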