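#' Count colonies in a clonogenicity-assay image
#'
#' Replays the classic particle-analysis pipeline on a single-channel image:
#' large-scale background subtraction (Gaussian high-pass at a scale much
#' larger than a colony), Gaussian blur, Otsu thresholding to a binary mask,
#' 8-connected component labelling, and filtering of components by area and
#' circularity `4*pi*A/P^2` (perimeter from the component contour as computed
#' by EBImage's shape features).
#'
#' @param image Numeric matrix or `colony_image` (its `$image` is used).
#' @param blur_sigma Gaussian blur sigma in pixels (default 2).
#' @param area_range Accepted component area interval in pixels.
#' @param circularity_range Accepted circularity interval; values slightly
#'   above 1 occur for small rasterized disks, so the default upper bound is
#'   1.2.
#' @param background_sigma Scale of the high-pass background estimate; the
#'   default, 10x the square root of the maximum accepted area, is much
#'   larger than any accepted colony. Set to `NULL` to skip background
#'   subtraction.
#' @return A `colony_count` list: `count`, `components` (tibble with per-
#'   component area, perimeter, circularity, accepted flag), `mask` (labelled
#'   matrix), `threshold` (Otsu cut on the processed image).
#' @export
count_colonies <- function(image, blur_sigma = 2, area_range = c(50, Inf),
                           circularity_range = c(0.5, 1.2),
                           background_sigma = NULL) {
  if (inherits(image, "colony_image")) image <- image$image
  stop_not(is.matrix(image) && is.numeric(image),
           "`image` must be a numeric single-channel matrix")
  stop_not(length(area_range) == 2 && area_range[1] <= area_range[2] &&
             area_range[1] >= 0, "invalid `area_range`")
  stop_not(length(circularity_range) == 2 &&
             circularity_range[1] <= circularity_range[2] &&
             circularity_range[1] >= 0, "invalid `circularity_range`")
  img <- image
  if (is.null(background_sigma) && is.finite(area_range[2])) {
    background_sigma <- 10 * sqrt(area_range[2])
  }
  if (!is.null(background_sigma) && is.finite(background_sigma)) {
    # gblur's brush (2*ceil(3*sigma)+1 pixels) must fit inside the image
    background_sigma <- min(background_sigma, (min(dim(img)) - 3) / 6)
    bg <- EBImage::gblur(EBImage::Image(img), sigma = background_sigma)
    img <- img - EBImage::imageData(bg)
  }
  if (blur_sigma > 0) {
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = blur_sigma))
  }
  # Otsu needs values in [0, 1]
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  thr <- EBImage::otsu(EBImage::Image(scaled))
  mask <- scaled > thr
  if (!any(mask)) {
    return(structure(list(count = 0L,
                          components = tibble::tibble(
                            label = integer(), area = numeric(),
                            perimeter = numeric(), circularity = numeric(),
                            accepted = logical()),
                          mask = matrix(0L, nrow(image), ncol(image)),
                          threshold = thr),
                     class = "colony_count"))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  feats <- EBImage::computeFeatures.shape(lab)
  area <- feats[, "s.area"]
  per <- vapply(EBImage::ocontour(lab), chain_perimeter, numeric(1))
  circ <- 4 * pi * area / pmax(per, 1)^2
  accepted <- area >= area_range[1] & area <= area_range[2] &
    circ >= circularity_range[1] & circ <= circularity_range[2]
  structure(list(count = sum(accepted),
                 components = tibble::tibble(
                   label = seq_along(area), area = unname(area),
                   perimeter = unname(per), circularity = unname(circ),
                   accepted = unname(accepted)),
                 mask = EBImage::imageData(lab), threshold = thr),
            class = "colony_count")
}

#' Normalize colony counts to the control condition
#'
#' Divides each well's colony count by the mean count of the control
#' condition of its parental line.
#'
#' @param counts Tibble with columns `condition`, `count`, and optionally
#'   `line` (parental line; a single line is assumed when absent).
#' @param control Control condition label.
#' @return The tibble with an added `normalized` column.
#' @export
normalize_colonies <- function(counts, control = "control") {
  stop_not(all(c("condition", "count") %in% names(counts)),
           "`counts` needs columns condition, count")
  if (!"line" %in% names(counts)) counts$line <- "line1"
  stop_not(control %in% counts$condition,
           "control condition '%s' missing", control)
  ctrl_means <- counts %>%
    dplyr::filter(.data$condition == control) %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(ctrl_mean = mean(.data$count), .groups = "drop")
  missing <- setdiff(unique(counts$line), ctrl_means$line)
  stop_not(length(missing) == 0, "line(s) without control wells: %s",
           paste(missing, collapse = ", "))
  stop_not(all(ctrl_means$ctrl_mean > 0), "zero mean control count")
  counts %>%
    dplyr::left_join(ctrl_means, by = "line") %>%
    dplyr::mutate(normalized = .data$count / .data$ctrl_mean) %>%
    dplyr::select(-"ctrl_mean")
}

#' Classify cells from an intensity table and summarise proportions
#'
#' Drops cells with a nuclear area below `min_area` (strictly smaller), calls
#' each remaining cell positive/negative per channel against the supplied
#' thresholds, maps the combination to a class (default: Epi = NANOG+SOX17-,
#' PrE = NANOG-SOX17+, anything else `other`), and reports per-replicate
#' proportions with mean and standard error across replicates.
#'
#' @param cells Tibble with `cell_id`, `area_um2`, `replicate` and one column
#'   per channel.
#' @param thresholds Named numeric vector of per-channel intensity thresholds
#'   (a cell is positive when strictly above).
#' @param min_area Nuclear area filter in square micrometres (default 40;
#'   cells with smaller area are removed).
#' @param classes Named list mapping class names to named logical vectors of
#'   required channel positivity, e.g.
#'   `list(Epi = c(NANOG = TRUE, SOX17 = FALSE))`. Cells matching no class
#'   are `other`.
#' @return A `cell_classification` list: `cells` (with `class` column),
#'   `proportions` (per replicate x class), `summary` (class mean proportion
#'   with `sem` across replicates).
#' @export
classify_cells <- function(cells, thresholds, min_area = 40,
                           classes = list(
                             Epi = c(NANOG = TRUE, SOX17 = FALSE),
                             PrE = c(NANOG = FALSE, SOX17 = TRUE))) {
  stop_not(all(c("area_um2", "replicate") %in% names(cells)),
           "`cells` needs columns area_um2 and replicate")
  stop_not(length(thresholds) > 0 && !is.null(names(thresholds)),
           "`thresholds` must be a named numeric vector")
  stop_not(all(names(thresholds) %in% names(cells)),
           "threshold channel(s) missing from the table")
  kept <- cells[cells$area_um2 >= min_area, ]
  stop_not(nrow(kept) > 0, "no cells survive the area filter")
  pos <- vapply(names(thresholds),
                function(ch) kept[[ch]] > thresholds[[ch]],
                logical(nrow(kept)))
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1,
                                       dimnames = list(NULL, names(thresholds)))
  cls <- rep("other", nrow(kept))
  for (nm in names(classes)) {
    req <- classes[[nm]]
    match_all <- rep(TRUE, nrow(kept))
    for (ch in names(req)) match_all <- match_all & (pos[, ch] == req[[ch]])
    cls[match_all] <- nm
  }
  kept$class <- cls
  levels_all <- c(names(classes), "other")
  props <- kept %>%
    dplyr::count(.data$replicate, class = factor(.data$class,
                                                 levels = levels_all)) %>%
    tidyr::complete(.data$replicate, .data$class, fill = list(n = 0)) %>%
    dplyr::group_by(.data$replicate) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  summary <- props %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     sem = sd(.data$proportion) /
                       sqrt(dplyr::n_distinct(props$replicate)),
                     .groups = "drop")
  structure(list(cells = kept, proportions = props, summary = summary,
                 thresholds = thresholds, min_area = min_area),
            class = "cell_classification")
}

# Perimeter of an 8-connected contour chain with the Vossepoel-Smeulders
# step correction (0.948 per axis step, 1.340 per diagonal step); corrects
# the staircase bias of raw boundary-pixel counts, Crofton-style.
chain_perimeter <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(1)
  d <- xy[c(2:n, 1), , drop = FALSE] - xy
  stepd <- abs(d[, 1]) + abs(d[, 2])
  0.948 * sum(stepd == 1) + 1.340 * sum(stepd == 2)
}

# 1-D Otsu threshold on a numeric vector (histogram-based).
otsu_1d <- function(x, n_bins = 256) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  for (k in seq_len(length(mids) - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):length(p)] * mids[(k + 1):length(p)]) / w1
    between <- w0 * w1 * (m0 - m1)^2
    if (between > best) {
      best <- between
      thr <- (mids[k] + mids[k + 1]) / 2
    }
  }
  thr
}

#' Suggest a bisecting intensity threshold for a bimodal marker
#'
#' Finds the deepest density minimum between the two highest modes of a
#' Gaussian-kernel density estimate; on unimodal densities it falls back to a
#' histogram Otsu threshold and flags the fallback.
#'
#' @param x Numeric intensities (>= 50 values, non-constant).
#' @return Scalar threshold with attribute `fallback` (TRUE when the density
#'   was unimodal and Otsu was used).
#' @export
suggest_threshold <- function(x) {
  stop_not(length(x) >= 50, "need >= 50 values")
  stop_not(sd(x) > 0, "constant input: no threshold exists")
  dens <- density(x, n = 512)
  y <- dens$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_max) < 2) {
    thr <- otsu_1d(x)
    attr(thr, "fallback") <- TRUE
    return(thr)
  }
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- seq(lo, hi)[which.min(y[lo:hi])]
  thr <- dens$x[valley]
  attr(thr, "fallback") <- FALSE
  thr
}
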