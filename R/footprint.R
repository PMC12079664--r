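#' Query delta vector: mutant minus wild type at a timepoint
#'
#' Per-gene difference of mean log2 expression between a mutant and the
#' wild-type line at the stated condition (typically after 24 h of
#' differentiation). Expression values must be positive (TPM-like); log2 is
#' taken without a pseudocount.
#'
#' @param expr Long expression tibble (`gene`, `genotype`, `condition`,
#'   `tpm`).
#' @param mutant,wild_type Genotype labels to compare.
#' @param condition Condition label (default `"N2B27_24h"`).
#' @return Tibble `gene`, `delta`. Warns on single-replicate input.
#' @export
query_delta <- function(expr, mutant = "mutant", wild_type = "wt",
                        condition = "N2B27_24h") {
  sel <- expr$condition == condition & expr$genotype %in% c(mutant, wild_type)
  stop_not(any(expr$condition == condition & expr$genotype == mutant) &&
             any(expr$condition == condition & expr$genotype == wild_type),
           "condition '%s' missing for one of the genotypes", condition)
  dat <- expr[sel, ]
  n_rep <- dat %>%
    dplyr::count(.data$gene, .data$genotype) %>%
    dplyr::pull(.data$n)
  if (any(n_rep < 2)) {
    rlang::warn("single-replicate input: delta computed without averaging over replicates")
  }
  dat %>%
    dplyr::group_by(.data$gene, .data$genotype) %>%
    dplyr::summarise(m = mean(log2(.data$tpm)), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "genotype", values_from = "m") %>%
    dplyr::transmute(gene = .data$gene,
                     delta = .data[[mutant]] - .data[[wild_type]])
}

fp_one <- function(footprints, pathway) {
  fp <- footprints[footprints$pathway == pathway, ]
  stop_not(nrow(fp) > 0, "pathway '%s' absent from footprints", pathway)
  fp
}

#' Pathway activity of a query delta vector
#'
#' The ratio between the summed expression changes of the query and of the
#' pathway-defining knockout over the pathway's footprint genes:
#' `a_P = sum(delta_query[S_P]) / sum(delta_def[S_P])`.
#'
#' @param delta Query delta tibble (`gene`, `delta`) from [query_delta()].
#' @param footprints A `pathway_footprints` tibble (`pathway`, `gene`,
#'   `delta`).
#' @param pathway Pathway name.
#' @return Scalar activity.
#' @export
pathway_activity <- function(delta, footprints, pathway) {
  fp <- fp_one(footprints, pathway)
  denom <- sum(fp$delta)
  stop_not(abs(denom) > .Machine$double.eps^0.5,
           "degenerate footprint: defining deltas of '%s' sum to zero",
           pathway)
  q <- delta$delta[match(fp$gene, delta$gene)]
  q[is.na(q)] <- 0
  sum(q) / denom
}

#' Spearman correlation of a query with the pathway-defining knockout
#'
#' Rank correlation between the query's deltas and the defining knockout's
#' deltas over the footprint gene set, with average ranks on ties. Undefined
#' (NA, with a warning) when either vector is constant.
#'
#' @inheritParams pathway_activity
#' @return Scalar Spearman rho in `[-1, 1]`, or NA.
#' @export
footprint_correlation <- function(delta, footprints, pathway) {
  fp <- fp_one(footprints, pathway)
  q <- delta$delta[match(fp$gene, delta$gene)]
  ok <- !is.na(q)
  stop_not(sum(ok) >= 3, "need >= 3 genes with defined values")
  if (sd(q[ok]) == 0 || sd(fp$delta[ok]) == 0) {
    rlang::warn(sprintf("constant vector for pathway '%s': correlation undefined",
                        pathway))
    return(NA_real_)
  }
  cor(q[ok], fp$delta[ok], method = "spearman")
}

#' Footprint panel: activity and correlation per query and pathway
#'
#' Scores each query mutant against every pathway footprint after batch
#' correction: when a batch's wild-type reference delta is supplied, it is
#' subtracted from each query delta of that batch before scoring.
#'
#' @param queries Named list of query delta tibbles (`gene`, `delta`), or a
#'   single delta tibble.
#' @param footprints A `pathway_footprints` tibble.
#' @param batch Optional character vector mapping each query to a batch
#'   (recycled); used with `wt_reference`.
#' @param wt_reference Optional named list of wild-type reference deltas per
#'   batch, subtracted from queries of the matching batch.
#' @return A `footprint_result` tibble: `query`, `pathway`, `activity`,
#'   `spearman`. Pathways whose defining deltas sum to zero are dropped with
#'   a warning (tile missing).
#' @export
footprint_panel <- function(queries, footprints, batch = NULL,
                            wt_reference = NULL) {
  if (is.data.frame(queries)) queries <- list(query = queries)
  stop_not(length(queries) >= 1, "no queries supplied")
  if (is.null(names(queries))) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  if (!is.null(batch)) batch <- rep_len(batch, length(queries))
  pathways <- unique(footprints$pathway)
  out <- purrr::imap_dfr(queries, function(q, nm) {
    if (!is.null(batch) && !is.null(wt_reference)) {
      b <- batch[[match(nm, names(queries))]]
      ref <- wt_reference[[b]]
      if (!is.null(ref)) {
        adj <- ref$delta[match(q$gene, ref$gene)]
        adj[is.na(adj)] <- 0
        q <- dplyr::mutate(q, delta = .data$delta - adj)
      }
    }
    purrr::map_dfr(pathways, function(p) {
      act <- tryCatch(pathway_activity(q, footprints, p),
                      medsift_error = function(e) {
                        rlang::warn(conditionMessage(e))
                        NA_real_
                      })
      if (is.na(act)) return(NULL)
      tibble::tibble(query = nm, pathway = p, activity = act,
                     spearman = suppressWarnings(
                       footprint_correlation(q, footprints, p)))
    })
  })
  structure(out, class = c("footprint_result", class(out)))
}
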