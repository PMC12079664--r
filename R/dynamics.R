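#' Expression change of a marker panel between two conditions
#'
#' Per-marker difference of mean log2 expression, `cond_to - cond_from`, for
#' one genotype.
#'
#' @param expr Long expression tibble (`gene`, `condition`, `tpm`, optionally
#'   `genotype`).
#' @param markers Marker panel (default the seven-gene naive panel,
#'   [naive_marker_panel()]).
#' @param cond_from,cond_to Condition labels (change is to minus from).
#' @param genotype Optional genotype to restrict to.
#' @return Tibble `gene`, `change` in panel order.
#' @export
marker_change <- function(expr, markers = naive_marker_panel(),
                          cond_from = "2i", cond_to = "N2B27_24h",
                          genotype = NULL) {
  if (!is.null(genotype)) expr <- expr[expr$genotype == genotype, ]
  missing <- setdiff(markers, unique(expr$gene))
  stop_not(length(missing) == 0, "markers absent from expression data: %s",
           paste(missing, collapse = ", "))
  stop_not(all(c(cond_from, cond_to) %in% expr$condition),
           "both conditions must be present")
  dat <- expr[expr$gene %in% markers &
                expr$condition %in% c(cond_from, cond_to), ]
  means <- dat %>%
    dplyr::group_by(.data$gene, .data$condition) %>%
    dplyr::summarise(m = mean(log2(.data$tpm)), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  means <- means[match(markers, means$gene), ]
  tibble::tibble(gene = markers,
                 change = means[[cond_to]] - means[[cond_from]])
}

#' Estimate a differentiation delay against a reference time course
#'
#' Builds reference change-to-time-t vectors `reference(t) - reference(0)` on
#' a fine time grid (linear interpolation between sampled timepoints),
#' standardizes each marker dimension by its standard deviation over the
#' reference course, and computes the normalized Euclidean distance
#' `D(t) = ||(q - ref_change(t)) / s|| / sqrt(m)` between the query change
#' vector and each grid point. The optimum `t*` is the grid argmin (earliest
#' on ties) and the delay is `delta = t* - nominal_h`. For plotting, the
#' curve is additionally min-max rescaled to `[0, 1]`; the rescaling is
#' monotone and leaves the argmin unchanged.
#'
#' @param change Marker change tibble from [marker_change()] (`gene`,
#'   `change`).
#' @param reference A `reference_timecourse`.
#' @param grid_step_h Search grid resolution in hours (default 0.1).
#' @param nominal_h Nominal differentiation duration in hours (default 24).
#' @return A `delay_estimate` list: `delta_h`, `t_star`, `d_min`, `curve`
#'   (tibble `time_h`, `distance`, `distance_scaled`), `markers_used`.
#' @export
estimate_delay <- function(change, reference, grid_step_h = 0.1,
                           nominal_h = 24) {
  stop_not(inherits(reference, "reference_timecourse"),
           "`reference` must be a reference_timecourse")
  markers <- intersect(change$gene, setdiff(names(reference), "time_h"))
  stop_not(length(markers) > 0, "no panel marker shared with the reference")
  grid <- seq(0, max(reference$time_h), by = grid_step_h)
  ref <- reference_at(reference, grid)[, markers, drop = FALSE]
  ref0 <- ref[1, ]
  ref_change <- sweep(ref, 2, ref0)
  s <- apply(ref, 2, sd)
  flat <- s == 0
  if (any(flat)) {
    rlang::warn(sprintf("flat reference for marker(s) %s: dropped",
                        paste(markers[flat], collapse = ", ")))
    markers <- markers[!flat]
    stop_not(length(markers) > 0, "all markers flat in the reference")
    ref_change <- ref_change[, markers, drop = FALSE]
    s <- s[!flat]
  }
  q <- change$change[match(markers, change$gene)]
  z <- sweep(sweep(ref_change, 2, q, FUN = function(r, qq) r - qq),
             2, s, "/")
  d <- sqrt(rowSums(z^2)) / sqrt(length(markers))
  i <- which.min(d)  # which.min returns the earliest index on ties
  rng <- range(d)
  scaled <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else rep(0, length(d))
  structure(list(delta_h = grid[i] - nominal_h, t_star = grid[i],
                 d_min = d[i],
                 curve = tibble::tibble(time_h = grid, distance = d,
                                        distance_scaled = scaled),
                 markers_used = markers, nominal_h = nominal_h,
                 grid_step_h = grid_step_h),
            class = "delay_estimate")
}

#' Slopes of regulation between mutant and wild type
#'
#' Per-gene ratio of the mutant's log2 expression change over differentiation
#' to the wild type's: `s_g = lfc_mut(g) / lfc_wt(g)`. An attenuated mutant
#' response gives slopes below one. Genes with `|lfc_wt| <= epsilon` are
#' excluded and reported in the result's attributes.
#'
#' @param wt_fc,mut_fc Fold-change tibbles (`gene`, `log2fc`).
#' @param selection `"top_down"` / `"top_up"` (the `n_top` genes with the
#'   strongest negative / positive wild-type fold change) or `"markers"`.
#' @param markers Marker panel used when `selection = "markers"`.
#' @param n_top Selection size for the top rules (default 100).
#' @param epsilon Wild-type fold-change floor for the denominator (default
#'   0.1 log2 units).
#' @return A `slope_distribution` tibble (`gene`, `wt_log2fc`, `mut_log2fc`,
#'   `slope`) with attributes `selection`, `excluded` (genes dropped by the
#'   epsilon rule) and `epsilon`.
#' @export
regulation_slopes <- function(wt_fc, mut_fc,
                              selection = c("top_down", "top_up", "markers"),
                              markers = naive_marker_panel(), n_top = 100,
                              epsilon = 0.1) {
  selection <- match.arg(selection)
  joined <- dplyr::inner_join(
    dplyr::select(wt_fc, "gene", wt_log2fc = "log2fc"),
    dplyr::select(mut_fc, "gene", mut_log2fc = "log2fc"), by = "gene")
  pick <- switch(selection,
    markers = joined[joined$gene %in% markers, ],
    top_down = dplyr::slice_min(joined, .data$wt_log2fc, n = n_top,
                                with_ties = FALSE),
    top_up = dplyr::slice_max(joined, .data$wt_log2fc, n = n_top,
                              with_ties = FALSE))
  stop_not(nrow(pick) > 0, "empty selection")
  excluded <- pick$gene[abs(pick$wt_log2fc) <= epsilon]
  pick <- pick[abs(pick$wt_log2fc) > epsilon, ]
  stop_not(nrow(pick) > 0, "all selected genes below the epsilon floor")
  out <- dplyr::mutate(pick, slope = .data$mut_log2fc / .data$wt_log2fc)
  structure(out, class = c("slope_distribution", class(out)),
            selection = selection, excluded = excluded, epsilon = epsilon)
}

#' Mode of the fold-change ratio distribution for a target set
#'
#' Computes, per target gene, the linear-scale ratio of mutant to wild-type
#' expression fold change, `r_g = 2^(log2fc_mut - log2fc_wt)`, restricted to
#' one direction (up- or downregulated genes in the wild type), and estimates
#' the distribution mode as the argmax of a Gaussian-kernel density (Silverman
#' bandwidth) on a 512-point grid spanning the ratio range.
#'
#' @param wt_fc,mut_fc Fold-change tibbles (`gene`, `log2fc`).
#' @param target_set Target set from [define_target_set()] (`gene`,
#'   `direction`).
#' @param direction `"up"` or `"down"`.
#' @return A `ratio_mode` list: `ratios` (tibble `gene`, `ratio`), `mode`,
#'   `bandwidth`, `direction`, `n`.
#' @export
fc_ratio_mode <- function(wt_fc, mut_fc, target_set,
                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- target_set$gene[target_set$direction == direction]
  stop_not(length(genes) >= 10,
           "< 10 genes in the '%s' direction set: mode unstable", direction)
  wt <- wt_fc$log2fc[match(genes, wt_fc$gene)]
  mut <- mut_fc$log2fc[match(genes, mut_fc$gene)]
  ok <- !is.na(wt) & !is.na(mut)
  stop_not(sum(ok) >= 10, "< 10 genes with fold changes in both tables")
  r <- 2^(mut[ok] - wt[ok])
  if (diff(range(r)) == 0) {
    mode <- r[1]
    bw <- NA_real_
  } else {
    bw <- stats::bw.nrd0(r)
    dens <- density(r, bw = bw, n = 512, from = min(r), to = max(r))
    mode <- dens$x[which.max(dens$y)]
  }
  structure(list(ratios = tibble::tibble(gene = genes[ok], ratio = r),
                 mode = mode, bandwidth = bw, direction = direction,
                 n = sum(ok)),
            class = "ratio_mode")
}
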