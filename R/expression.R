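#' Simple differential-expression contract
#'
#' A light-weight two-group test for the downstream statistics, which consume
#' only (log2fc, padj): per gene, log2fc is the difference of group means of
#' log2(x + 1), p comes from a Welch (unequal-variance) t-test on the same
#' scale, and padj is Benjamini-Hochberg over the tested genes.
#'
#' @param expr Long expression tibble with columns `gene`, `tpm` (or `value`)
#'   and a grouping column.
#' @param contrast Character vector `c(group_a, group_b)`; log2fc is a minus
#'   b.
#' @param group_col Name of the grouping column (default `"condition"`).
#' @return A fold-change tibble: `gene`, `log2fc`, `p`, `padj`.
#' @export
simple_de <- function(expr, contrast, group_col = "condition") {
  stop_not(length(contrast) == 2, "`contrast` must name two groups")
  value_col <- if ("tpm" %in% names(expr)) "tpm" else "value"
  stop_not(all(c("gene", value_col, group_col) %in% names(expr)),
           "`expr` needs columns gene, %s, %s", value_col, group_col)
  a <- expr[expr[[group_col]] == contrast[1], ]
  b <- expr[expr[[group_col]] == contrast[2], ]
  stop_not(nrow(a) > 0 && nrow(b) > 0, "contrast group absent from data")
  genes <- sort(unique(expr$gene))
  av <- split(log2(a[[value_col]] + 1), factor(a$gene, levels = genes))
  bv <- split(log2(b[[value_col]] + 1), factor(b$gene, levels = genes))
  n_a <- lengths(av); n_b <- lengths(bv)
  stop_not(all(n_a >= 2) && all(n_b >= 2),
           "need >= 2 replicates per group for every gene")
  lfc <- vapply(genes, function(g) mean(av[[g]]) - mean(bv[[g]]), numeric(1))
  p <- vapply(genes, function(g) welch_p(av[[g]], bv[[g]]), numeric(1))
  tibble::tibble(gene = genes, log2fc = unname(lfc), p = unname(p),
                 padj = bh_adjust(unname(p)))
}

#' Define a target gene set from a fold-change table
#'
#' Selects genes with `|log2fc| > lfc_min` and `padj < padj_max`, partitioned
#' into up- (log2fc > 0) and downregulated subsets.
#'
#' @param fc Fold-change tibble (`gene`, `log2fc`, `padj`).
#' @param lfc_min Absolute log2 fold-change floor (default 1).
#' @param padj_max Adjusted p-value ceiling (default 0.05).
#' @return Tibble `gene`, `log2fc`, `padj`, `direction` (`"up"`/`"down"`).
#' @export
define_target_set <- function(fc, lfc_min = 1, padj_max = 0.05) {
  check_scalar_number(lfc_min, "lfc_min", lower = 0, strict_lower = TRUE)
  check_scalar_number(padj_max, "padj_max", lower = 0, strict_lower = TRUE)
  fc %>%
    dplyr::filter(abs(.data$log2fc) > lfc_min, .data$padj < padj_max) %>%
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) %>%
    dplyr::select("gene", "log2fc", "padj", "direction")
}

#' Quality-control filter for single-cell count matrices
#'
#' Removes barcodes with at most `min_genes` detected genes or a
#' mitochondrial read fraction of at least `max_mito` (i.e. retains cells
#' with strictly more detected genes than `min_genes` and strictly less
#' mitochondrial fraction than `max_mito`, matching removal at the
#' boundaries).
#'
#' @param counts Gene x cell matrix (dense or sparse) of non-negative integer
#'   counts with gene row names.
#' @param mito_genes Character vector of mitochondrial gene names (used to
#'   compute the per-cell mitochondrial fraction).
#' @param min_genes Detected-gene boundary (default 2500; cells at or below
#'   are removed).
#' @param max_mito Mitochondrial-fraction boundary (default 0.15; cells at or
#'   above are removed).
#' @return The filtered matrix; a warning is raised if no cell survives.
#' @export
sc_qc_filter <- function(counts, mito_genes = character(), min_genes = 2500,
                         max_mito = 0.15) {
  stop_not(!is.null(rownames(counts)), "`counts` needs gene row names")
  detected <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mito <- intersect(mito_genes, rownames(counts))
  mito_frac <- if (length(mito) > 0) {
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
  } else rep(0, ncol(counts))
  keep <- detected > min_genes & mito_frac < max_mito
  if (!any(keep)) {
    rlang::warn("all cells removed by QC filter; returning an empty matrix")
  }
  counts[, keep, drop = FALSE]
}

#' Library-size normalization with log1p transform
#'
#' Each cell's counts are divided by its total count, multiplied by 10,000,
#' and log1p-transformed: `value = log1p(count / cell_total * 1e4)`.
#'
#' @param counts Gene x cell count matrix with cell column names.
#' @return Matrix of normalized values; `sum(expm1(column)) == 1e4` for every
#'   cell.
#' @export
sc_normalize <- function(counts) {
  totals <- Matrix::colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero) > 0 && is.null(colnames(counts)))
    zero <- which(totals == 0)
  stop_not(all(totals > 0), "zero-total cell(s): %s",
           paste(zero, collapse = ", "))
  log1p(sweep(as.matrix(counts), 2, totals, "/") * 1e4)
}

#' Marker test between two cell groups
#'
#' Per-gene Wilcoxon rank-sum test restricted to genes whose group-mean
#' difference in log1p-normalized expression is at least `min_diff`
#' (in absolute value), with Benjamini-Hochberg adjustment over the tested
#' genes.
#'
#' @param normalized Normalized matrix from [sc_normalize()].
#' @param groups Factor/character vector over cells with exactly two levels,
#'   each with at least 20 cells.
#' @param min_diff Minimal absolute group-mean difference to test (default
#'   0.5).
#' @return Tibble `gene`, `mean_diff` (group1 - group2), `p`, `padj`, sorted
#'   by `padj`; empty when no gene passes the floor.
#' @export
sc_marker_test <- function(normalized, groups, min_diff = 0.5) {
  groups <- as.factor(groups)
  stop_not(nlevels(groups) == 2, "`groups` must have exactly two levels")
  stop_not(all(table(groups) >= 20), "each group needs >= 20 cells")
  g1 <- levels(groups)[1]
  m1 <- rowMeans(normalized[, groups == g1, drop = FALSE])
  m2 <- rowMeans(normalized[, groups != g1, drop = FALSE])
  diff <- m1 - m2
  test_genes <- rownames(normalized)[abs(diff) >= min_diff]
  if (length(test_genes) == 0) {
    return(tibble::tibble(gene = character(), mean_diff = numeric(),
                          p = numeric(), padj = numeric()))
  }
  p <- vapply(test_genes, function(g) {
    wilcox.test(normalized[g, groups == g1],
                normalized[g, groups != g1], exact = FALSE)$p.value
  }, numeric(1))
  tibble::tibble(gene = test_genes, mean_diff = diff[test_genes],
                 p = unname(p), padj = bh_adjust(unname(p))) %>%
    dplyr::arrange(.data$padj)
}
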