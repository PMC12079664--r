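#' Total-count normalization of a guide count table
#'
#' Rescales every sample column so that its total equals the mean of the
#' original column totals (MAGeCK-style "total" normalization).
#'
#' @param counts Tibble with `guide_id` plus numeric sample columns (and any
#'   annotation columns such as `gene`, `is_control`, which are passed
#'   through).
#' @param sample_cols Character vector of sample column names; defaults to all
#'   numeric columns.
#' @return The table with sample columns rescaled (real-valued).
#' @export
total_count_normalize <- function(counts, sample_cols = NULL) {
  sample_cols <- sample_cols %||%
    names(counts)[vapply(counts, is.numeric, logical(1))]
  stop_not(length(sample_cols) >= 1, "no sample columns to normalize")
  totals <- vapply(sample_cols, function(s) sum(counts[[s]]), numeric(1))
  zero <- sample_cols[totals == 0]
  stop_not(length(zero) == 0, "all-zero sample column(s): %s",
           paste(zero, collapse = ", "))
  target <- mean(totals)
  for (s in sample_cols) counts[[s]] <- counts[[s]] * target / totals[[s]]
  counts
}

#' Guide-level log2 fold change, ranks and percentiles
#'
#' Computes `log2((sorted + pseudocount) / (reference + pseudocount))` per
#' guide, ranks guides by descending enrichment (ties broken stably by guide
#' identifier) and assigns percentiles `u = rank / N` over the full library,
#' non-targeting controls included.
#'
#' @param counts Normalized guide count table ([total_count_normalize()]).
#' @param sorted,reference Names of the sorted and reference sample columns.
#' @param pseudocount Added to both columns (default 1).
#' @return A guide stats tibble: `guide_id`, `gene`, `is_control`, `log2fc`,
#'   `rank`, `percentile`.
#' @export
guide_log2fc <- function(counts, sorted, reference = "unsorted",
                         pseudocount = 1) {
  stop_not(all(c("guide_id", sorted, reference) %in% names(counts)),
           "`counts` must contain columns guide_id, %s, %s", sorted, reference)
  stop_not(!anyDuplicated(counts$guide_id), "duplicated guide_id entries")
  lfc <- log2((counts[[sorted]] + pseudocount) /
                (counts[[reference]] + pseudocount))
  ord <- order(-lfc, counts$guide_id)
  rank <- integer(length(lfc))
  rank[ord] <- seq_along(lfc)
  tibble::tibble(guide_id = counts$guide_id,
                 gene = if ("gene" %in% names(counts)) counts$gene else
                   NA_character_,
                 is_control = if ("is_control" %in% names(counts))
                   counts$is_control else is.na(counts$gene),
                 log2fc = lfc, rank = rank,
                 percentile = rank / length(lfc))
}

# rho for one gene: sorted percentiles u, library-wide, alpha cutoff.
rra_rho <- function(u, alpha) {
  n <- length(u)
  if (n == 0) return(1)
  u <- sort(u)
  keep <- which(u <= alpha)
  if (length(keep) == 0) return(1)
  # P(Beta(k, n - k + 1) <= u_(k)): k-th order statistic of n uniforms
  min(pbeta(u[keep], keep, n - keep + 1))
}

#' Alpha-RRA gene scores
#'
#' Robust rank aggregation with an alpha cutoff: for a gene with guide
#' percentiles u(1) <= ... <= u(n), only guides with u <= alpha participate;
#' beta_k = P(Beta(k, n - k + 1) <= u(k)) is the probability that the k-th
#' order statistic of n uniforms is at most u(k), and rho is the minimum
#' beta_k over participating k. Genes with no participating guide get rho = 1.
#'
#' @param stats Guide stats tibble from [guide_log2fc()] (percentiles over
#'   the full library, controls included).
#' @param alpha Percentile cutoff in (0, 1] (default 0.25).
#' @return Tibble `gene`, `rho`, `n_guides` (targeting genes only).
#' @export
alpha_rra_score <- function(stats, alpha = 0.25) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE)
  stats %>%
    dplyr::filter(!is.na(.data$gene)) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(rho = rra_rho(.data$percentile, alpha),
                     n_guides = dplyr::n(), .groups = "drop")
}

#' Permutation p-values and FDR for alpha-RRA scores
#'
#' Null rho values are generated by resampling gene-sized sets of percentiles
#' from the observed percentile pool (without replacement within a draw) and
#' recomputing rho. Genes with the same number of guides share a null
#' distribution (the draws are exchangeable across same-size genes).
#' `p = (1 + #\{rho_null <= rho_obs\}) / (1 + n_perm)`; FDR is
#' Benjamini-Hochberg across genes. Deterministic under `seed`.
#'
#' @param stats Guide stats tibble ([guide_log2fc()]).
#' @param alpha Percentile cutoff passed to the rho computation.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return A gene score tibble: `gene`, `rho`, `p_perm`, `fdr`,
#'   `lfc_alphamean`, `n_guides`.
#' @export
permutation_fdr <- function(stats, alpha = 0.25, n_perm = 1000, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  stop_not(n_perm >= 100, "`n_perm` must be >= 100 (unstable tail otherwise)")
  scores <- alpha_rra_score(stats, alpha)
  pool <- stats$percentile
  with_seed(seed, {
    null_for_size <- lapply(sort(unique(scores$n_guides)), function(n) {
      vapply(seq_len(n_perm), function(i) {
        rra_rho(sample(pool, n, replace = FALSE), alpha)
      }, numeric(1))
    })
    names(null_for_size) <- as.character(sort(unique(scores$n_guides)))
    p <- vapply(seq_len(nrow(scores)), function(i) {
      null <- null_for_size[[as.character(scores$n_guides[i])]]
      (1 + sum(null <= scores$rho[i])) / (1 + n_perm)
    }, numeric(1))
    lfc <- gene_lfc_alphamean(stats, alpha)
    out <- scores %>%
      dplyr::mutate(p_perm = p, fdr = bh_adjust(p)) %>%
      dplyr::left_join(lfc, by = "gene") %>%
      dplyr::select("gene", "rho", "p_perm", "fdr", "lfc_alphamean",
                    "n_guides") %>%
      dplyr::arrange(.data$rho)
    out
  })
}

#' Alpha-mean gene log2 fold change
#'
#' Gene LFC is the mean log2 fold change of guides with percentile
#' `u <= alpha`; if no guide passes the cutoff, the mean over all of the
#' gene's guides is used (documented fallback).
#'
#' @inheritParams permutation_fdr
#' @return Tibble `gene`, `lfc_alphamean`, `n_pass`.
#' @export
gene_lfc_alphamean <- function(stats, alpha = 0.25) {
  stats %>%
    dplyr::filter(!is.na(.data$gene)) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_pass = sum(.data$percentile <= alpha),
      lfc_alphamean = if (sum(.data$percentile <= alpha) > 0)
        mean(.data$log2fc[.data$percentile <= alpha]) else mean(.data$log2fc),
      .groups = "drop") %>%
    dplyr::select("gene", "lfc_alphamean", "n_pass")
}

#' Compound hit selection across sorting conditions
#'
#' A gene is a hit iff its FDR is at most `primary` in at least one condition,
#' or at most `secondary` in at least `min_secondary` conditions. Genes
#' missing from a condition's table count as FDR = 1 there (conservative).
#'
#' @param fdr_tables Named list of gene score tibbles (one per condition),
#'   each with columns `gene` and `fdr`.
#' @param primary Primary FDR threshold (default 0.05).
#' @param secondary Secondary FDR threshold (default 0.2).
#' @param min_secondary Minimum number of conditions meeting `secondary`
#'   (default 2).
#' @return A hit tibble: `gene`, one `fdr_<condition>` column per condition,
#'   `n_primary`, `n_secondary`, `is_hit`.
#' @export
select_hits <- function(fdr_tables, primary = 0.05, secondary = 0.2,
                        min_secondary = 2) {
  stop_not(is.list(fdr_tables) && length(fdr_tables) >= 1,
           "`fdr_tables` must be a non-empty list of score tables")
  if (is.null(names(fdr_tables)) || any(names(fdr_tables) == "")) {
    names(fdr_tables) <- paste0("cond", seq_along(fdr_tables))
  }
  universe <- sort(unique(unlist(lapply(fdr_tables, function(t) t$gene))))
  out <- tibble::tibble(gene = universe)
  for (nm in names(fdr_tables)) {
    tab <- fdr_tables[[nm]]
    stop_not(all(c("gene", "fdr") %in% names(tab)),
             "condition '%s' lacks gene/fdr columns", nm)
    idx <- match(universe, tab$gene)
    fdr <- tab$fdr[idx]
    fdr[is.na(fdr)] <- 1
    out[[paste0("fdr_", nm)]] <- fdr
  }
  fmat <- as.matrix(out[, -1, drop = FALSE])
  out$n_primary <- rowSums(fmat <= primary)
  out$n_secondary <- rowSums(fmat <= secondary)
  out$is_hit <- out$n_primary >= 1 | out$n_secondary >= min_secondary
  out
}

#' Targeting vs control guide enrichment summary
#'
#' Compares the log2 fold-change distributions of gene-targeting and
#' non-targeting control guides: class means, empirical CDFs and a two-sample
#' Wilcoxon rank-sum statistic with its normal-approximation z and p.
#'
#' @param stats Guide stats tibble ([guide_log2fc()]).
#' @return A `control_enrichment` list: `summary` (per-class n, mean, sd),
#'   `rank_sum` (tibble with `statistic`, `z`, `p`), and `ecdf` functions per
#'   class.
#' @export
control_enrichment_summary <- function(stats) {
  targ <- stats$log2fc[!stats$is_control]
  ctrl <- stats$log2fc[stats$is_control]
  stop_not(length(targ) > 0 && length(ctrl) > 0,
           "both targeting and control guides are required")
  w <- wilcox.test(targ, ctrl, exact = FALSE, correct = FALSE)
  n1 <- length(targ); n2 <- length(ctrl)
  mu <- n1 * n2 / 2
  # normal approximation with tie correction
  allv <- c(targ, ctrl)
  ties <- table(allv)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (unname(w$statistic) - mu) / sqrt(sigma2)
  structure(list(
    summary = tibble::tibble(
      class = c("targeting", "control"),
      n = c(n1, n2),
      mean_log2fc = c(mean(targ), mean(ctrl)),
      sd_log2fc = c(sd(targ), sd(ctrl))),
    rank_sum = tibble::tibble(statistic = unname(w$statistic), z = z,
                              p = w$p.value),
    ecdf = list(targeting = stats::ecdf(targ), control = stats::ecdf(ctrl))),
    class = "control_enrichment")
}

#' Score a full screen dataset across all sorted conditions
#'
#' Convenience pipeline: total-count normalization, guide log2 fold changes
#' per sorted sample against the unsorted reference, alpha-RRA with
#' permutation FDR per condition, and the compound hit rule.
#'
#' @param dataset A `screen_dataset` from [simulate_screen()], or a list with
#'   `counts` and `samples` in the same layout.
#' @param alpha,n_perm,seed Passed to [permutation_fdr()].
#' @param pseudocount Passed to [guide_log2fc()].
#' @param primary,secondary,min_secondary Passed to [select_hits()].
#' @return A `screen_scores` list: `guide_stats` (named list per condition),
#'   `gene_scores` (named list per condition), `hits` (hit tibble).
#' @export
screen_score <- function(dataset, alpha = 0.25, n_perm = 1000, seed = 1,
                         pseudocount = 1, primary = 0.05, secondary = 0.2,
                         min_secondary = 2) {
  counts <- total_count_normalize(dataset$counts)
  sorted <- dataset$samples$sample[dataset$samples$sorted]
  stop_not(length(sorted) >= 1, "dataset has no sorted samples")
  guide_stats <- lapply(sorted, function(s) {
    guide_log2fc(counts, sorted = s, reference = "unsorted",
                 pseudocount = pseudocount)
  })
  names(guide_stats) <- sorted
  gene_scores <- lapply(seq_along(sorted), function(i) {
    permutation_fdr(guide_stats[[i]], alpha = alpha, n_perm = n_perm,
                    seed = seed + i)
  })
  names(gene_scores) <- sorted
  hits <- select_hits(gene_scores, primary = primary, secondary = secondary,
                      min_secondary = min_secondary)
  structure(list(guide_stats = guide_stats, gene_scores = gene_scores,
                 hits = hits),
            class = "screen_scores")
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
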