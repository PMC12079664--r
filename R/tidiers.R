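# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @exportS3Method generics::tidy
tidy.delay_estimate <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.delay_estimate <- function(x, ...) {
  tibble::tibble(delta_h = x$delta_h, t_star = x$t_star, d_min = x$d_min,
                 n_markers = length(x$markers_used))
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, threshold = x$threshold, j = x$j,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method generics::tidy
tidy.mixture_assignment <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.mixture_assignment <- function(x, ...) {
  tibble::tibble(mean_1 = x$components$mean_log10[1],
                 mean_2 = x$components$mean_log10[2],
                 sd_1 = x$components$sd_log10[1],
                 sd_2 = x$components$sd_log10[2],
                 weight_1 = x$components$weight[1],
                 n_unassigned = sum(is.na(x$cells$component)),
                 loglik = x$loglik)
}

#' @exportS3Method generics::tidy
tidy.colony_count <- function(x, ...) x$components

#' @exportS3Method generics::glance
glance.colony_count <- function(x, ...) {
  tibble::tibble(count = x$count, n_components = nrow(x$components),
                 threshold = x$threshold)
}

#' @exportS3Method generics::tidy
tidy.ratio_mode <- function(x, ...) x$ratios

#' @exportS3Method generics::glance
glance.ratio_mode <- function(x, ...) {
  tibble::tibble(mode = x$mode, bandwidth = x$bandwidth,
                 direction = x$direction, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.control_enrichment <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.control_enrichment <- function(x, ...) x$rank_sum

#' Plot the differentiation-delay distance curve
#'
#' @param object A `delay_estimate`.
#' @param ... Unused.
#' @return A ggplot: min-max-scaled distance over reference time, with the
#'   optimum and the nominal duration marked.
#' @exportS3Method ggplot2::autoplot
autoplot.delay_estimate <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$time_h, y = .data$distance_scaled)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$t_star, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$nominal_h, colour = "grey60") +
    ggplot2::labs(x = "reference time (h)",
                  y = "normalized Euclidean distance",
                  title = sprintf("delay = %+.1f h", object$delta_h)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve with the Youden-optimal point
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve; the Youden-optimal operating point is
#'   highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  best <- object$points[object$points$threshold == object$threshold, ]
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70",
                         linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f, J = %.3f at %.3g",
                                  object$auc, object$j, object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted intensity mixture with assignment bands
#'
#' @param object A `mixture_assignment`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot histogram of log10 intensity coloured by assignment, with
#'   the fitted component densities overlaid.
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_assignment <- function(object, bins = 50, ...) {
  cells <- dplyr::mutate(
    object$cells, log10_intensity = log10(.data$intensity),
    assignment = factor(ifelse(is.na(.data$component), "unassigned",
                               paste0("component ", .data$component))))
  grid <- seq(min(cells$log10_intensity), max(cells$log10_intensity),
              length.out = 256)
  comp <- object$components
  dens <- purrr::map_dfr(1:2, function(k) {
    tibble::tibble(x = grid, component = paste0("component ", k),
                   y = comp$weight[k] *
                     dnorm(grid, comp$mean_log10[k], comp$sd_log10[k]))
  })
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$log10_intensity)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density),
                                         fill = .data$assignment),
                            bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::labs(x = "log10 intensity", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a footprint panel as a tile grid
#'
#' Tile fill encodes pathway activity, tile size the Spearman correlation
#' with the pathway-defining knockout.
#'
#' @param panel A `footprint_result` tibble from [footprint_panel()].
#' @return A ggplot tile grid (query x pathway).
#' @export
plot_footprint_grid <- function(panel) {
  ggplot2::ggplot(panel,
                  ggplot2::aes(x = .data$pathway, y = .data$query)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$spearman),
                                     colour = .data$activity),
                        shape = 15) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red", midpoint = 0) +
    ggplot2::scale_size_area(max_size = 12, limits = c(0, 1)) +
    ggplot2::labs(size = "|Spearman|", colour = "activity") +
    ggplot2::theme_minimal()
}

#' Plot a slope-of-regulation distribution
#'
#' @param slopes A `slope_distribution` from [regulation_slopes()].
#' @return A ggplot violin/box plot of the per-gene slopes with the unity
#'   line marked.
#' @export
plot_slope_distribution <- function(slopes) {
  dat <- tibble::as_tibble(slopes)
  dat$selection <- attr(slopes, "selection")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$selection, y = .data$slope)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "slope of regulation (mutant / wild type)") +
    ggplot2::theme_minimal()
}
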