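# Shared in-code fixtures for the test suite.

# Guide stats table with given percentiles (one gene + optional filler).
make_guide_stats <- function(u, gene = "geneA", fill = numeric()) {
  all_u <- c(u, fill)
  tibble::tibble(
    guide_id = sprintf("sg%03d", seq_along(all_u)),
    gene = c(rep(gene, length(u)), rep(NA_character_, length(fill))),
    is_control = c(rep(FALSE, length(u)), rep(TRUE, length(fill))),
    log2fc = -all_u,  # consistent ordering: smaller u = stronger enrichment
    rank = rank(all_u, ties.method = "first"),
    percentile = all_u)
}

# Small long-format expression table: one gene, two conditions, n reps each.
make_expr <- function(genes, values_by_condition, n_rep = 2,
                      genotype = "wt") {
  purrr::imap_dfr(values_by_condition, function(vals, cond) {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      tibble::tibble(gene = genes, sample = paste0(cond, "_r", r),
                     genotype = genotype, condition = cond, replicate = r,
                     tpm = vals)
    })
  })
}

# Fold-change tibble from named log2fc vector.
make_fc <- function(lfc, padj = 0.001) {
  tibble::tibble(gene = names(lfc), log2fc = unname(lfc),
                 p = padj, padj = padj)
}

expect_tibble <- function(x) {
  expect_s3_class(x, "tbl_df")
}
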