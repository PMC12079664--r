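#' Ground truth for a simulated sorting screen
#'
#' Describes the conditions of a pooled CRISPR reporter screen: a library of
#' `n_genes` genes with `guides_per_gene` guides each plus `n_controls`
#' non-targeting control guides, a per-gene effect on reporter log-intensity,
#' and a set of FACS gates. Each cell's reporter log-intensity is modelled as
#' Normal(effect of its guide's gene, `baseline_sd`); a gate keeps the
#' corresponding tail fraction of the population.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides per gene (library convention, default 4).
#' @param n_controls Number of non-targeting control guides (default 1000).
#' @param effect Per-gene shift of reporter log-intensity; scalar or length
#'   `n_genes`. Negative values reduce reporter expression. Controls always
#'   have effect exactly 0.
#' @param baseline_sd Standard deviation of reporter log-intensity within a
#'   clone.
#' @param library_dispersion Coefficient of variation of guide abundances in
#'   the plasmid library (0 = perfectly uniform).
#' @param depth Total sequencing reads per sample.
#' @param gates Tibble with columns `fraction`, `day`, `direction`
#'   (`"low"`/`"high"`). Defaults to the four low gates: 1% and 5% at days 6
#'   and 9.
#' @param seed Integer seed; all randomness in [simulate_screen()] flows from
#'   it.
#' @return A `screen_truth` list.
#' @export
screen_truth <- function(n_genes = 500, guides_per_gene = 4, n_controls = 1000,
                         effect = 0, baseline_sd = 1, library_dispersion = 0.25,
                         depth = 1e6, gates = default_gates(), seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  guides_per_gene <- check_count(guides_per_gene, "guides_per_gene")
  n_controls <- check_count(n_controls, "n_controls", min = 0L)
  check_scalar_number(baseline_sd, "baseline_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(library_dispersion, "library_dispersion", lower = 0)
  check_scalar_number(depth, "depth", lower = 0, strict_lower = TRUE)
  stop_not(is.data.frame(gates) && nrow(gates) > 0,
           "`gates` must be a non-empty data frame (empty gate list rejected)")
  stop_not(all(c("fraction", "day") %in% names(gates)),
           "`gates` needs columns `fraction` and `day`")
  if (!"direction" %in% names(gates)) gates$direction <- "low"
  stop_not(all(gates$fraction > 0 & gates$fraction < 1),
           "gate fractions must lie in (0, 1)")
  stop_not(all(gates$direction %in% c("low", "high")),
           "gate direction must be 'low' or 'high'")
  effect <- rep_len(effect, n_genes)
  stop_not(all(is.finite(effect)), "gene effects must be finite")
  structure(list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 n_controls = n_controls, effect = effect,
                 baseline_sd = baseline_sd,
                 library_dispersion = library_dispersion, depth = depth,
                 gates = tibble::as_tibble(gates), seed = seed),
            class = "screen_truth")
}

#' @rdname screen_truth
#' @export
default_gates <- function() {
  tidyr::expand_grid(fraction = c(0.01, 0.05), day = c(6, 9),
                     direction = "low")
}

gate_sample_name <- function(direction, fraction, day) {
  sprintf("%s_%gpct_d%d", direction, fraction * 100, as.integer(day))
}

#' Simulate a sorted-population CRISPR screen
#'
#' Draws guide count tables for an unsorted reference sample and one sample
#' per FACS gate. Guide abundances in the library are Gamma-distributed with
#' the stated dispersion; a gate's selection probability for a guide is the
#' Gaussian tail probability of its gene's reporter-intensity distribution
#' beyond the population gate cutoff, and counts are multinomial draws from
#' the selected-cell guide frequencies at the stated depth.
#'
#' @param truth A [screen_truth()] object.
#' @return A `screen_dataset` list with elements `counts` (tibble: `guide_id`,
#'   `gene`, `is_control`, `unsorted`, one column per gate), `samples` (sample
#'   metadata) and `truth`.
#' @export
simulate_screen <- function(truth) {
  stop_not(inherits(truth, "screen_truth"), "`truth` must be a screen_truth")
  with_seed(truth$seed, {
    genes <- sprintf("gene%04d", seq_len(truth$n_genes))
    guide_gene <- rep(genes, each = truth$guides_per_gene)
    guide_eff <- rep(truth$effect, each = truth$guides_per_gene)
    n_target <- length(guide_gene)
    guide_id <- c(sprintf("%s_sg%d", guide_gene,
                          rep(seq_len(truth$guides_per_gene), truth$n_genes)),
                  sprintf("ctrl%05d", seq_len(truth$n_controls)))
    gene <- c(guide_gene, rep(NA_character_, truth$n_controls))
    eff <- c(guide_eff, rep(0, truth$n_controls))
    n_guides <- length(guide_id)

    w <- if (truth$library_dispersion > 0) {
      shape <- 1 / truth$library_dispersion^2
      rgamma(n_guides, shape = shape, rate = shape)
    } else rep(1, n_guides)
    w <- w / sum(w)

    counts <- tibble::tibble(guide_id = guide_id, gene = gene,
                             is_control = is.na(gene))
    counts$unsorted <- as.integer(rmultinom(1, size = truth$depth, prob = w))

    sample_meta <- tibble::tibble(sample = "unsorted", fraction = NA_real_,
                                  day = NA_integer_, direction = NA_character_,
                                  sorted = FALSE)
    sd <- truth$baseline_sd
    for (i in seq_len(nrow(truth$gates))) {
      g <- truth$gates[i, ]
      # population gate cutoff: quantile of the guide-weighted Gaussian mixture
      cdf <- function(q) sum(w * pnorm(q, mean = eff, sd = sd))
      target <- if (g$direction == "low") g$fraction else 1 - g$fraction
      q <- stats::uniroot(function(x) cdf(x) - target,
                          lower = min(eff) - 12 * sd,
                          upper = max(eff) + 12 * sd, tol = 1e-10)$root
      p_sel <- if (g$direction == "low") {
        pnorm(q, mean = eff, sd = sd)
      } else {
        pnorm(q, mean = eff, sd = sd, lower.tail = FALSE)
      }
      freq <- w * p_sel
      freq <- freq / sum(freq)
      nm <- gate_sample_name(g$direction, g$fraction, g$day)
      counts[[nm]] <- as.integer(rmultinom(1, size = truth$depth, prob = freq))
      sample_meta <- dplyr::bind_rows(
        sample_meta,
        tibble::tibble(sample = nm, fraction = g$fraction,
                       day = as.integer(g$day), direction = g$direction,
                       sorted = TRUE))
    }
    structure(list(counts = counts, samples = sample_meta, truth = truth),
              class = "screen_dataset")
  })
}

#' Ground truth for simulated bulk expression
#'
#' Houses the planted quantities the dynamics and footprint estimators must
#' recover: a global response-attenuation factor `attenuation` (mutant log2
#' fold changes are `attenuation` times the wild-type ones), a differentiation
#' time shift `delay_h` (mutant naive markers follow the reference time course
#' evaluated at `24 - delay_h` hours), and per-pathway planted activities.
#'
#' @param attenuation Global mutant response scaling c in (0, 1]; fold changes
#'   on the log2 scale are multiplied by c in the mutant.
#' @param delay_h Planted differentiation delay in hours (positive = mutant
#'   lags).
#' @param pathway_activities Named numeric vector: planted activity per
#'   pathway, applied as a shift of the mutant's differentiated expression
#'   along the pathway-defining delta vector.
#' @param noise_sd Measurement noise on the log2 scale.
#' @param n_replicates Replicates per genotype x condition (>= 2).
#' @param seed Integer seed.
#' @return An `expression_truth` list.
#' @export
expression_truth <- function(attenuation = 1, delay_h = 0,
                             pathway_activities = NULL, noise_sd = 0.1,
                             n_replicates = 3, seed = 1) {
  check_scalar_number(attenuation, "attenuation", lower = 0, strict_lower = TRUE)
  check_scalar_number(delay_h, "delay_h")
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  if (!is.null(pathway_activities)) {
    stop_not(is.numeric(pathway_activities) &&
               !is.null(names(pathway_activities)),
             "`pathway_activities` must be a named numeric vector")
  }
  structure(list(attenuation = attenuation, delay_h = delay_h,
                 pathway_activities = pathway_activities, noise_sd = noise_sd,
                 n_replicates = n_replicates, seed = seed),
            class = "expression_truth")
}

#' Default naive pluripotency marker panel
#'
#' The seven-gene naive marker panel used for differentiation-delay
#' estimation.
#' @return Character vector of marker gene names.
#' @export
naive_marker_panel <- function() {
  c("Prdm14", "Tfcp2l1", "Klf4", "Tbx3", "Nanog", "Zfp42", "Esrrb")
}

#' Simulate a reference differentiation time course
#'
#' Per-marker monotone sigmoidal decay of log2 expression from its t = 0
#' level, emulating a high-time-resolution naive-marker reference dataset.
#' The profile is `floor + (initial - floor) / (1 + (rate * t)^shape)`, so a
#' marker with rate r reaches half of its total decline at t = 1/r; rate 0
#' gives a constant profile.
#'
#' @param markers Marker gene names (default the naive panel).
#' @param t_max_h,step_h Time grid in hours; t = 0 is always included.
#' @param rates Decay rates (1/h), scalar or one per marker; must be >= 0.
#' @param initial,floor Log2 expression at t = 0 and asymptote; scalar or per
#'   marker.
#' @param shape Sigmoid steepness (> 0).
#' @param noise_sd Optional Gaussian jitter on the stored values (default 0,
#'   i.e. a noise-free reference).
#' @param seed Seed for the jitter; ignored when `noise_sd = 0`.
#' @return A `reference_timecourse`: tibble with `time_h` plus one column per
#'   marker.
#' @export
simulate_reference_timecourse <- function(markers = naive_marker_panel(),
                                          t_max_h = 96, step_h = 2,
                                          rates = 1 / 24, initial = 8,
                                          floor = 2, shape = 2,
                                          noise_sd = 0, seed = NULL) {
  stop_not(length(markers) >= 1, "need at least one marker")
  check_scalar_number(step_h, "step_h", lower = 0, strict_lower = TRUE)
  check_scalar_number(t_max_h, "t_max_h", lower = step_h)
  rates <- rep_len(rates, length(markers))
  stop_not(all(is.finite(rates) & rates >= 0),
           "decay rates must be finite and >= 0 (negative rates rejected)")
  initial <- rep_len(initial, length(markers))
  floor <- rep_len(floor, length(markers))
  stop_not(all(initial >= floor), "`initial` must be >= `floor` per marker")
  check_scalar_number(shape, "shape", lower = 0, strict_lower = TRUE)
  t <- unique(c(0, seq(0, t_max_h, by = step_h)))
  vals <- vapply(seq_along(markers), function(i) {
    floor[i] + (initial[i] - floor[i]) / (1 + (rates[i] * t)^shape)
  }, numeric(length(t)))
  if (noise_sd > 0) {
    vals <- with_seed(seed, vals + rnorm(length(vals), sd = noise_sd))
  }
  out <- tibble::as_tibble(as.data.frame(vals, col.names = markers))
  names(out) <- markers
  out <- dplyr::bind_cols(tibble::tibble(time_h = t), out)
  structure(out, class = c("reference_timecourse", class(out)),
            rates = setNames(rates, markers),
            initial = setNames(initial, markers),
            floor = setNames(floor, markers), shape = shape)
}

reference_at <- function(reference, t) {
  markers <- setdiff(names(reference), "time_h")
  out <- vapply(markers, function(m) {
    approx(reference$time_h, reference[[m]], xout = t, rule = 2)$y
  }, numeric(length(t)))
  matrix(out, nrow = length(t), dimnames = list(NULL, markers))
}

#' Simulate pathway-defining footprint gene sets
#'
#' Draws, for each pathway, a footprint gene set and its defining knockout
#' delta vector (expression difference knockout - wild type after 24 h of
#' differentiation). Deltas are drawn with a coherent positive mean so the
#' summed defining delta — the pathway-activity denominator — is bounded away
#' from zero.
#'
#' @param pathways Pathway names.
#' @param genes_per_pathway Footprint size (default 50).
#' @param delta_mean,delta_sd Distribution of per-gene defining deltas (log2).
#' @param seed Integer seed.
#' @return A `pathway_footprints` tibble with columns `pathway`, `gene`,
#'   `delta`.
#' @export
simulate_pathway_footprints <- function(pathways = c("FGF", "mTOR", "Wnt",
                                                     "Notch"),
                                        genes_per_pathway = 50,
                                        delta_mean = 0.5, delta_sd = 1,
                                        seed = 1) {
  genes_per_pathway <- check_count(genes_per_pathway, "genes_per_pathway")
  with_seed(seed, {
    out <- purrr::map_dfr(pathways, function(p) {
      tibble::tibble(
        pathway = p,
        gene = sprintf("%s_fp%02d", p, seq_len(genes_per_pathway)),
        delta = rnorm(genes_per_pathway, delta_mean, delta_sd))
    })
    structure(out, class = c("pathway_footprints", class(out)))
  })
}

#' Simulate bulk expression for a wild-type / mutant differentiation design
#'
#' Generates linear-scale (TPM-like) expression for two genotypes in
#' pluripotency medium (`2i`) and after 24 h of differentiation
#' (`N2B27_24h`). Wild-type log2 fold changes over differentiation are drawn
#' from a Gaussian signature; mutant fold changes are `attenuation` times the
#' wild-type ones on the log2 scale. Naive-marker levels follow the reference
#' time course evaluated at `24 - delay_h` hours for the mutant and 24 h for
#' the wild type. Planted pathway activities shift the mutant's
#' differentiated expression along each pathway-defining delta vector.
#'
#' @param truth An [expression_truth()] object.
#' @param reference A [simulate_reference_timecourse()] result; its markers
#'   become the naive panel in the generated data.
#' @param footprints Optional [simulate_pathway_footprints()] tibble; pathway
#'   gene sets must be disjoint from the marker panel.
#' @param n_background Number of unstructured background genes.
#' @param signature_sd SD of the wild-type log2 fold-change signature.
#' @return A `bulk_expression` list: `expression` (long tibble: `gene`,
#'   `sample`, `genotype`, `condition`, `replicate`, `tpm`), `wt_fc` and
#'   `mut_fc` (fold-change tibbles `gene`, `log2fc`, `p`, `padj`), `markers`,
#'   `footprints`, `truth`.
#' @export
simulate_bulk_expression <- function(truth, reference, footprints = NULL,
                                     n_background = 300, signature_sd = 1.5) {
  stop_not(inherits(truth, "expression_truth"),
           "`truth` must be an expression_truth")
  stop_not(inherits(reference, "reference_timecourse"),
           "`reference` must be a reference_timecourse")
  markers <- setdiff(names(reference), "time_h")
  fp_genes <- character()
  if (!is.null(footprints)) {
    fp_genes <- footprints$gene
    overlap <- intersect(fp_genes, markers)
    stop_not(length(overlap) == 0,
             "pathway gene sets overlap the marker panel: %s",
             paste(overlap, collapse = ", "))
    acts <- truth$pathway_activities
    if (!is.null(acts)) {
      stop_not(all(names(acts) %in% unique(footprints$pathway)),
               "pathway_activities name pathways absent from `footprints`")
    }
  }
  with_seed(truth$seed, {
    bg <- if (n_background > 0) sprintf("bg%04d", seq_len(n_background)) else
      character()
    genes <- c(markers, fp_genes, bg)
    n <- length(genes)

    baseline <- setNames(rnorm(n, 6, 2), genes)
    ref0 <- reference_at(reference, 0)[1, markers]
    baseline[markers] <- ref0

    wt_lfc <- setNames(rnorm(n, 0, signature_sd), genes)
    ref24 <- reference_at(reference, 24)[1, markers]
    wt_lfc[markers] <- ref24 - ref0
    mut_lfc <- truth$attenuation * wt_lfc
    ref_mut <- reference_at(reference, 24 - truth$delay_h)[1, markers]
    mut_lfc[markers] <- ref_mut - ref0

    shift <- setNames(rep(0, n), genes)
    if (!is.null(footprints) && !is.null(truth$pathway_activities)) {
      for (p in names(truth$pathway_activities)) {
        rows <- footprints[footprints$pathway == p, ]
        shift[rows$gene] <- shift[rows$gene] +
          truth$pathway_activities[[p]] * rows$delta
      }
    }

    design <- tidyr::expand_grid(genotype = c("wt", "mutant"),
                                 condition = c("2i", "N2B27_24h"),
                                 replicate = seq_len(truth$n_replicates))
    expr <- purrr::pmap_dfr(design, function(genotype, condition, replicate) {
      mu <- baseline
      if (condition == "N2B27_24h") {
        mu <- mu + if (genotype == "wt") wt_lfc else mut_lfc + shift
      }
      log2val <- mu + if (truth$noise_sd > 0)
        rnorm(n, sd = truth$noise_sd) else 0
      tibble::tibble(gene = genes,
                     sample = sprintf("%s_%s_r%d", genotype, condition,
                                      replicate),
                     genotype = genotype, condition = condition,
                     replicate = replicate, tpm = 2^log2val)
    })

    fc_for <- function(geno) {
      dat <- expr[expr$genotype == geno, ]
      wide <- tidyr::pivot_wider(dat, id_cols = "gene",
                                 names_from = c("condition", "replicate"),
                                 values_from = "tpm")
      a_cols <- grep("^N2B27_24h_", names(wide))
      b_cols <- grep("^2i_", names(wide))
      lfc <- numeric(nrow(wide)); pv <- numeric(nrow(wide))
      for (i in seq_len(nrow(wide))) {
        a <- log2(as.numeric(wide[i, a_cols]))
        b <- log2(as.numeric(wide[i, b_cols]))
        lfc[i] <- mean(a) - mean(b)
        pv[i] <- welch_p(a, b)
      }
      tibble::tibble(gene = wide$gene, log2fc = lfc, p = pv,
                     padj = bh_adjust(pv))
    }
    structure(list(expression = expr, wt_fc = fc_for("wt"),
                   mut_fc = fc_for("mutant"), markers = markers,
                   footprints = footprints, truth = truth),
              class = "bulk_expression")
  })
}

# Welch p-value robust to zero-variance (noise-free) input.
welch_p <- function(a, b) {
  if (isTRUE(all.equal(var(a), 0)) && isTRUE(all.equal(var(b), 0))) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(t.test(a, b)$p.value, error = function(e) 1)
}

#' Ground truth for simulated induction traces
#'
#' @param n_cells Number of cells (>= 2; both fates are represented by
#'   construction).
#' @param true_threshold Induction level above which (strictly) fate is PrE.
#' @param frame_interval_min Imaging interval in minutes (default 10).
#' @param noise_sd Additive intensity noise per frame.
#' @param n_frames Frames per trace.
#' @param seed Integer seed.
#' @return A `trace_truth` list.
#' @export
trace_truth <- function(n_cells = 100, true_threshold = 1,
                        frame_interval_min = 10, noise_sd = 0.05,
                        n_frames = 61, seed = 1) {
  n_cells <- check_count(n_cells, "n_cells", min = 2L)
  check_scalar_number(true_threshold, "true_threshold", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(frame_interval_min, "frame_interval_min", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  n_frames <- check_count(n_frames, "n_frames", min = 7L)
  structure(list(n_cells = n_cells, true_threshold = true_threshold,
                 frame_interval_min = frame_interval_min, noise_sd = noise_sd,
                 n_frames = n_frames, seed = seed), class = "trace_truth")
}

#' Simulate rise-and-fall fluorescence induction traces
#'
#' Each cell follows a pulse `A * (t/t_peak) * exp(1 - t/t_peak)` (peak height
#' A at `t_peak`) plus Gaussian frame noise. Fate is `PrE` iff the noise-free
#' peak strictly exceeds `true_threshold` (a peak exactly at the threshold is
#' labelled `other`). Half the cells are drawn above and half below the
#' threshold so both fates are always represented.
#'
#' @param truth A [trace_truth()] object.
#' @return A `trace_set` list: `traces` (long tibble `cell_id`, `frame`,
#'   `time_min`, `intensity`, `fate`), `cells` (per-cell truth) and `truth`.
#' @export
simulate_traces <- function(truth) {
  stop_not(inherits(truth, "trace_truth"), "`truth` must be a trace_truth")
  with_seed(truth$seed, {
    n <- truth$n_cells
    n_hi <- ceiling(n / 2)
    thr <- truth$true_threshold
    amp <- c(thr * (1 + runif(n_hi, 0.05, 1)),
             thr * runif(n - n_hi, 0.2, 0.95))
    ord <- sample.int(n)
    amp <- amp[ord]
    t_total <- (truth$n_frames - 1) * truth$frame_interval_min
    t_peak <- runif(n, 0.35, 0.65) * t_total
    time_min <- (seq_len(truth$n_frames) - 1) * truth$frame_interval_min
    fate <- ifelse(amp > thr, "PrE", "other")
    traces <- purrr::map_dfr(seq_len(n), function(i) {
      x <- time_min / t_peak[i]
      clean <- amp[i] * x * exp(1 - x)
      tibble::tibble(cell_id = sprintf("cell%04d", i),
                     frame = seq_len(truth$n_frames), time_min = time_min,
                     intensity = clean +
                       if (truth$noise_sd > 0)
                         rnorm(truth$n_frames, sd = truth$noise_sd) else 0,
                     fate = fate[i])
    })
    cells <- tibble::tibble(cell_id = sprintf("cell%04d", seq_len(n)),
                            peak = amp, t_peak_min = t_peak, fate = fate)
    structure(list(traces = traces, cells = cells, truth = truth),
              class = "trace_set")
  })
}

#' Simulate a two-component fluorescence intensity mixture
#'
#' Log10 intensities are Normal per component; true component labels are
#' retained. Components are ordered by ascending mean, so swapping the input
#' order of (means, sds) yields the same sample up to labels.
#'
#' @param n_per_component Cells per component; scalar or length 2.
#' @param means,sds Component means and SDs on the log10-intensity scale.
#' @param seed Integer seed.
#' @return Tibble with `cell_id`, `component` (1 = lower mean), `log10_intensity`,
#'   `intensity`.
#' @export
simulate_mixture <- function(n_per_component = 500, means = c(2, 4),
                             sds = c(0.3, 0.3), seed = 1) {
  stop_not(length(means) == 2 && length(sds) == 2,
           "exactly two components are supported")
  stop_not(all(sds > 0), "component sds must be positive")
  stop_not(means[1] != means[2],
           "component means must be distinct (equal means are unidentifiable)")
  n_per_component <- rep_len(n_per_component, 2)
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; n_per_component <- n_per_component[ord]
  with_seed(seed, {
    lab <- rep(1:2, times = n_per_component)
    x <- rnorm(sum(n_per_component), mean = means[lab], sd = sds[lab])
    tibble::tibble(cell_id = sprintf("cell%05d", seq_along(x)),
                   component = lab, log10_intensity = x, intensity = 10^x)
  })
}

ellipse_perimeter <- function(a, b) {
  # Ramanujan's approximation
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Simulate a colony-assay image
#'
#' Places non-overlapping elliptical colonies (disks when `axis_ratio = 1`) on
#' a noisy background with an optional horizontal intensity gradient. Truth
#' records each colony's analytic area and circularity (4*pi*A/P^2, perimeter
#' by Ramanujan's approximation).
#'
#' @param n_colonies Number of colonies (0 gives an empty image).
#' @param radius_range Range of the minor semi-axis in pixels.
#' @param radii Optional explicit minor semi-axes, one per colony (overrides
#'   `radius_range`); useful for planting colonies on both sides of a size
#'   filter.
#' @param axis_ratio Major/minor axis ratio (1 = disk).
#' @param image_size `c(rows, cols)` in pixels.
#' @param noise_sd Gaussian pixel noise (image dynamic range is ~1).
#' @param background_gradient Intensity added linearly across columns.
#' @param colony_intensity,background Foreground/background levels.
#' @param seed Integer seed.
#' @param max_tries Placement retries before giving up.
#' @return A `colony_image` list: `image` (numeric matrix), `truth` (tibble of
#'   colony centres, axes, area, circularity), `params`.
#' @export
simulate_colony_image <- function(n_colonies = 5, radius_range = c(8, 15),
                                  radii = NULL,
                                  axis_ratio = 1, image_size = c(256, 256),
                                  noise_sd = 0.02, background_gradient = 0,
                                  colony_intensity = 0.8, background = 0.1,
                                  seed = 1, max_tries = 2000) {
  n_colonies <- check_count(n_colonies, "n_colonies", min = 0L)
  if (!is.null(radii)) {
    stop_not(length(radii) == n_colonies && all(radii > 0),
             "`radii` must give one positive radius per colony")
    radius_range <- range(c(radii, radius_range[1]))
  }
  stop_not(length(radius_range) == 2 && all(radius_range > 0) &&
             radius_range[1] <= radius_range[2], "invalid `radius_range`")
  check_scalar_number(axis_ratio, "axis_ratio", lower = 1)
  with_seed(seed, {
    nr <- image_size[1]; nc <- image_size[2]
    margin <- max(radius_range[2], radii) * axis_ratio + 2
    placed <- tibble::tibble(x = numeric(), y = numeric(), r = numeric())
    tries <- 0
    while (nrow(placed) < n_colonies) {
      tries <- tries + 1
      stop_not(tries <= max_tries,
               "could not place %d non-overlapping colonies in a %dx%d image",
               n_colonies, nr, nc)
      r <- if (!is.null(radii)) radii[nrow(placed) + 1] else
        runif(1, radius_range[1], radius_range[2])
      x <- runif(1, margin, nr - margin)
      y <- runif(1, margin, nc - margin)
      sep <- (r + placed$r) * axis_ratio + 4
      if (nrow(placed) == 0 ||
          all(sqrt((x - placed$x)^2 + (y - placed$y)^2) > sep)) {
        placed <- dplyr::bind_rows(placed, tibble::tibble(x = x, y = y, r = r))
      }
    }
    theta <- if (n_colonies > 0) runif(n_colonies, 0, pi) else numeric()
    img <- matrix(background, nr, nc) +
      background_gradient * matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
    for (i in seq_len(n_colonies)) {
      a <- placed$r[i] * axis_ratio; b <- placed$r[i]
      box_r <- ceiling(a) + 1
      xs <- max(1, floor(placed$x[i] - box_r)):min(nr, ceiling(placed$x[i] + box_r))
      ys <- max(1, floor(placed$y[i] - box_r)):min(nc, ceiling(placed$y[i] + box_r))
      dx <- outer(xs - placed$x[i], rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - placed$y[i])
      u <- dx * cos(theta[i]) + dy * sin(theta[i])
      v <- -dx * sin(theta[i]) + dy * cos(theta[i])
      inside <- (u / a)^2 + (v / b)^2 <= 1
      img[xs, ys][inside] <- colony_intensity
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
    truth <- tibble::tibble(
      x = placed$x, y = placed$y, minor = placed$r,
      major = placed$r * axis_ratio, angle = theta,
      area = pi * placed$r^2 * axis_ratio,
      circularity = 4 * pi * (pi * placed$r^2 * axis_ratio) /
        ellipse_perimeter(placed$r * axis_ratio, placed$r)^2)
    structure(list(image = img, truth = truth,
                   params = list(n_colonies = n_colonies,
                                 radius_range = radius_range,
                                 axis_ratio = axis_ratio,
                                 noise_sd = noise_sd,
                                 background_gradient = background_gradient,
                                 colony_intensity = colony_intensity,
                                 background = background, seed = seed)),
              class = "colony_image")
  })
}
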