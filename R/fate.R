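#' Rolling-average smoothing of fluorescence traces
#'
#' Centered rolling mean over `window` frames per cell; edges use shrinking
#' windows (the mean over the frames that fall inside the trace), so no
#' padding values are invented. `window = 1` is the identity.
#'
#' @param traces Long trace tibble (`cell_id`, `frame`, `intensity`, other
#'   columns passed through), or a `trace_set`.
#' @param window Odd window length (default 7 frames).
#' @return The tibble with `intensity` replaced by the smoothed values.
#' @export
smooth_trace <- function(traces, window = 7) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  window <- check_count(window, "window")
  stop_not(window %% 2 == 1, "`window` must be odd")
  lens <- table(traces$cell_id)
  stop_not(all(lens >= window),
           "trace(s) shorter than the smoothing window: %s",
           paste(names(lens)[lens < window], collapse = ", "))
  traces %>%
    dplyr::arrange(.data$cell_id, .data$frame) %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::mutate(intensity = zoo::rollapply(.data$intensity, window, mean,
                                             partial = TRUE)) %>%
    dplyr::ungroup()
}

#' Scalar fate-predictive feature per cell
#'
#' Summarises each (smoothed) trace by a scalar: `"peak"` (the trace maximum;
#' the natural summary of rise-and-fall induction dynamics) or
#' `"end_of_induction"` (the final frame's value).
#'
#' @param traces Long trace tibble (typically from [smooth_trace()]), with
#'   `cell_id`, `frame`, `intensity` and optionally `fate`.
#' @param feature `"peak"` or `"end_of_induction"`.
#' @return Tibble `cell_id`, `value`, and `fate` if present in the input.
#' @export
trace_feature <- function(traces, feature = "peak") {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  stop_not(feature %in% c("peak", "end_of_induction"),
           "unknown feature '%s'", feature)
  traces %>%
    dplyr::arrange(.data$cell_id, .data$frame) %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::summarise(
      value = if (feature == "peak") max(.data$intensity) else
        .data$intensity[dplyr::n()],
      fate = if ("fate" %in% names(traces)) .data$fate[1] else NA_character_,
      .groups = "drop")
}

#' ROC analysis with Youden's J optimal threshold
#'
#' Builds the ROC curve over all distinct feature values as candidate
#' thresholds (predicting the positive class when `feature > threshold`),
#' computes the AUC by the trapezoidal rule, and selects the threshold
#' maximizing Youden's `J = sensitivity + specificity - 1`; on ties the
#' lowest threshold is returned.
#'
#' @param features Numeric feature per observation.
#' @param labels Class labels; `positive` names the positive class.
#' @param positive Positive class label (default `"PrE"`).
#' @return A `roc_result` list: `points` (tibble `threshold`, `fpr`, `tpr`,
#'   `j`), `auc`, `threshold`, `j`, `n_pos`, `n_neg`.
#' @export
roc_youden <- function(features, labels, positive = "PrE") {
  stop_not(length(features) == length(labels),
           "features and labels must have equal length")
  pos <- labels == positive
  stop_not(any(pos) && any(!pos),
           "both classes must be present for ROC analysis")
  thr <- c(-Inf, sort(unique(features)))
  tpr <- vapply(thr, function(t) mean(features[pos] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(features[!pos] > t), numeric(1))
  # trapezoidal area over the (fpr, tpr) staircase; tied feature values
  # across classes form diagonal segments, giving the 1/2 tie convention
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * zoo::rollmean(tpr[ord], 2))
  j <- tpr + (1 - fpr) - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  structure(list(points = tibble::tibble(threshold = thr, fpr = fpr,
                                         tpr = tpr, j = j),
                 auc = auc, threshold = thr[best], j = j[best],
                 n_pos = sum(pos), n_neg = sum(!pos), positive = positive),
            class = "roc_result")
}

# One-dimensional two-component Gaussian EM on x; deterministic
# quantile-based initialization.
em_gmm2 <- function(x, tol = 1e-8, max_iter = 500) {
  mu <- unname(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * sd(x) / 10
  sigma <- rep(max(sd(x) / 2, .Machine$double.eps), 2)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    n1 <- sum(g); n2 <- length(x) - n1
    stop_not(n1 > 1e-8 && n2 > 1e-8,
             "EM degenerate: a component vanished (weights %.3g / %.3g)",
             n1 / length(x), n2 / length(x))
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                    sum((1 - g) * (x - mu[2])^2) / n2))
    stop_not(all(sigma > 1e-12),
             "EM degenerate: vanishing variance (sigma = %.3g / %.3g)",
             sigma[1], sigma[2])
    w <- c(n1, n2) / length(x)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll, iter = iter)
}

#' Gaussian-mixture genotype assignment with a posterior-certainty rule
#'
#' Fits a two-component Gaussian mixture to log10 fluorescence intensities by
#' expectation-maximization (quantile initialization at the 25th/75th
#' percentiles, tolerance 1e-8, at most 500 iterations) and assigns each cell
#' to its maximum-posterior component only when that posterior is at least
#' `posterior_min` (default 0.85); cells between the populations stay
#' unassigned. Components are reported in ascending order of mean.
#'
#' @param intensities Positive fluorescence intensities (>= 20 cells).
#' @param posterior_min Posterior certainty required for assignment.
#' @param seed Accepted for interface uniformity; the fit is deterministic
#'   (quantile initialization), so it has no effect.
#' @param tol,max_iter EM convergence controls.
#' @return A `mixture_assignment` list: `components` (tibble `component`,
#'   `mean_log10`, `sd_log10`, `weight`), `cells` (tibble `intensity`,
#'   `posterior_1`, `posterior_2`, `component` with NA = unassigned),
#'   `posterior_min`, `loglik`.
#' @export
gmm_assign <- function(intensities, posterior_min = 0.85, seed = NULL,
                       tol = 1e-8, max_iter = 500) {
  stop_not(length(intensities) >= 20, "need >= 20 cells")
  stop_not(all(intensities > 0), "intensities must be positive")
  check_scalar_number(posterior_min, "posterior_min", lower = 0.5, upper = 1)
  x <- log10(intensities)
  fit <- em_gmm2(x, tol = tol, max_iter = max_iter)
  ord <- order(fit$mu)
  mu <- fit$mu[ord]; sigma <- fit$sigma[ord]; w <- fit$w[ord]
  d1 <- w[1] * dnorm(x, mu[1], sigma[1])
  d2 <- w[2] * dnorm(x, mu[2], sigma[2])
  p1 <- d1 / (d1 + d2)
  comp <- ifelse(p1 >= posterior_min, 1L,
                 ifelse(1 - p1 >= posterior_min, 2L, NA_integer_))
  structure(list(
    components = tibble::tibble(component = 1:2, mean_log10 = mu,
                                sd_log10 = sigma, weight = w),
    cells = tibble::tibble(intensity = intensities, posterior_1 = p1,
                           posterior_2 = 1 - p1, component = comp),
    posterior_min = posterior_min, loglik = fit$loglik, iter = fit$iter),
    class = "mixture_assignment")
}
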