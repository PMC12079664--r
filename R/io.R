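#' Read and write gene sets in GMT format
#'
#' GMT is tab-delimited: one set per line as `name <TAB> description <TAB>
#' member1 <TAB> member2 ...`. The description is exactly field 2, so tabs
#' cannot occur inside it; reading and writing a valid file round-trips to
#' identity.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors with a `description`
#'   attribute per set.
#' @export
read_gmt <- function(path) {
  stop_not(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  stop_not(length(lines) > 0, "empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, character(1), 1)
  stop_not(!anyDuplicated(nm), "duplicate set names in %s: %s", path,
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    stop_not(length(f) >= 3, "GMT line for set '%s' has no members", f[[1]])
    members <- f[-(1:2)]
    attr(members, "description") <- f[[2]]
    members
  })
  names(sets) <- nm
  sets
}

#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute each; empty member lists are rejected).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  stop_not(is.list(sets) && length(sets) > 0 && !is.null(names(sets)),
           "`sets` must be a non-empty named list")
  stop_not(!anyDuplicated(names(sets)), "duplicate set names")
  lines <- vapply(names(sets), function(nm) {
    members <- sets[[nm]]
    stop_not(length(members) > 0, "set '%s' has an empty member list", nm)
    desc <- attr(members, "description") %||% ""
    paste(c(nm, desc, as.character(members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Tab-separated table readers and writers
#'
#' Thin wrappers around readr with the package's conventions: tab-separated,
#' header row, no row names.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_tsv_table()` returns a tibble; `write_tsv_table()` returns
#'   `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

stage_schemas <- function() {
  list(
    simulate_screen = list(required = c("seed"),
                           optional = c("n_genes", "guides_per_gene",
                                        "n_controls", "effect", "baseline_sd",
                                        "library_dispersion", "depth"),
                           stochastic = TRUE),
    screen = list(required = c("counts", "seed"),
                  optional = c("alpha", "n_perm", "primary_fdr",
                               "secondary_fdr", "min_secondary",
                               "pseudocount"),
                  stochastic = TRUE),
    footprint = list(required = c("expression", "footprints"),
                     optional = c("condition", "mutant", "wild_type"),
                     stochastic = FALSE),
    dynamics = list(required = c("expression", "reference"),
                    optional = c("markers", "grid_step_h", "nominal_h",
                                 "cond_from", "cond_to"),
                    stochastic = FALSE),
    fate = list(required = c("traces"),
                optional = c("window", "feature", "positive"),
                stochastic = FALSE),
    colonies = list(required = c("image"),
                    optional = c("blur_sigma", "area_min", "area_max",
                                 "circularity_min", "circularity_max"),
                    stochastic = FALSE),
    classify = list(required = c("cells", "thresholds"),
                    optional = c("min_area"),
                    stochastic = FALSE))
}

validate_config <- function(config) {
  stop_not(is.list(config), "config must be a list (or a YAML/JSON file path)")
  stop_not(!is.null(config$stage), "config lacks a `stage` field")
  schemas <- stage_schemas()
  stop_not(config$stage %in% names(schemas),
           "unknown stage '%s' (known: %s)", config$stage,
           paste(names(schemas), collapse = ", "))
  schema <- schemas[[config$stage]]
  keys <- setdiff(names(config), c("stage", "out_dir"))
  unknown <- setdiff(keys, c(schema$required, schema$optional))
  stop_not(length(unknown) == 0, "unknown config key(s) for stage '%s': %s",
           config$stage, paste(unknown, collapse = ", "))
  missing <- setdiff(schema$required, names(config))
  stop_not(length(missing) == 0,
           "stage '%s' is missing required field(s): %s%s", config$stage,
           paste(missing, collapse = ", "),
           if ("seed" %in% missing)
             " (stochastic stages need an explicit seed)" else "")
  stop_not(!is.null(config$out_dir), "config lacks an `out_dir` field")
  config
}

stage_log <- function(stage, msg) {
  message(sprintf("[medsift:%s] %s", stage, msg))
}

#' Run one pipeline stage from a configuration
#'
#' Validates a stage configuration against its schema (unknown keys rejected;
#' stochastic stages require an explicit seed), runs the stage, writes its
#' output tables into `out_dir` and saves a run manifest (stage, parameters,
#' seed, package version) alongside. Reruns with the same config are
#' byte-identical for deterministic stages.
#'
#' @param config A named list, or a path to a YAML or JSON file containing
#'   one. Required fields: `stage`, `out_dir`, plus the stage's own inputs
#'   (paths to TSV/CSV tables; see the stage schemas in the source).
#' @return Invisibly, a list with `outputs` (paths written) and `summary`
#'   (stage-specific key numbers), also written as `summary.json`.
#' @export
run_stage <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- validate_config(config)
  stage <- config$stage
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir)
  stage_log(stage, "starting")
  outputs <- character()
  summary <- list()

  if (stage == "simulate_screen") {
    truth <- screen_truth(
      n_genes = config$n_genes %||% 500,
      guides_per_gene = config$guides_per_gene %||% 4,
      n_controls = config$n_controls %||% 1000,
      effect = config$effect %||% 0,
      baseline_sd = config$baseline_sd %||% 1,
      library_dispersion = config$library_dispersion %||% 0.25,
      depth = config$depth %||% 1e6,
      seed = config$seed)
    ds <- simulate_screen(truth)
    outputs <- c(counts = write_tsv_table(ds$counts,
                                          file.path(out, "guide_counts.tsv")),
                 samples = write_tsv_table(ds$samples,
                                           file.path(out, "samples.tsv")))
    summary <- list(n_guides = nrow(ds$counts), n_samples = nrow(ds$samples))
  } else if (stage == "screen") {
    counts <- read_tsv_table(config$counts)
    samples <- tibble::tibble(
      sample = setdiff(names(counts)[vapply(counts, is.numeric, logical(1))],
                       "unsorted"))
    samples$sorted <- TRUE
    ds <- list(counts = counts, samples = samples)
    scores <- screen_score(
      ds, alpha = config$alpha %||% 0.25, n_perm = config$n_perm %||% 1000,
      seed = config$seed, pseudocount = config$pseudocount %||% 1,
      primary = config$primary_fdr %||% 0.05,
      secondary = config$secondary_fdr %||% 0.2,
      min_secondary = config$min_secondary %||% 2)
    gene_tables <- purrr::imap_dfr(scores$gene_scores,
                                   ~dplyr::mutate(.x, condition = .y))
    outputs <- c(gene_scores = write_tsv_table(
                   gene_tables, file.path(out, "gene_scores.tsv")),
                 hits = write_tsv_table(scores$hits,
                                        file.path(out, "hits.tsv")))
    summary <- list(n_genes = nrow(scores$hits),
                    n_hits = sum(scores$hits$is_hit))
  } else if (stage == "footprint") {
    expr <- read_tsv_table(config$expression)
    fps <- read_tsv_table(config$footprints)
    delta <- query_delta(expr, mutant = config$mutant %||% "mutant",
                         wild_type = config$wild_type %||% "wt",
                         condition = config$condition %||% "N2B27_24h")
    grid <- footprint_panel(list(query = delta), fps)
    outputs <- c(panel = write_tsv_table(grid,
                                         file.path(out, "footprint.tsv")))
    summary <- list(n_pathways = nrow(grid),
                    top_pathway = grid$pathway[which.max(abs(grid$activity))])
  } else if (stage == "dynamics") {
    expr <- read_tsv_table(config$expression)
    ref_tbl <- read_tsv_table(config$reference)
    ref <- structure(ref_tbl, class = c("reference_timecourse",
                                        class(ref_tbl)))
    markers <- config$markers %||% naive_marker_panel()
    change <- marker_change(expr, markers = markers,
                            cond_from = config$cond_from %||% "2i",
                            cond_to = config$cond_to %||% "N2B27_24h")
    est <- estimate_delay(change, ref,
                          grid_step_h = config$grid_step_h %||% 0.1,
                          nominal_h = config$nominal_h %||% 24)
    outputs <- c(curve = write_tsv_table(est$curve,
                                         file.path(out, "delay_curve.tsv")))
    summary <- list(delta_h = est$delta_h, t_star = est$t_star,
                    d_min = est$d_min)
  } else if (stage == "fate") {
    traces <- read_tsv_table(config$traces)
    sm <- smooth_trace(traces, window = config$window %||% 7)
    feats <- trace_feature(sm, feature = config$feature %||% "peak")
    roc <- roc_youden(feats$value, feats$fate,
                      positive = config$positive %||% "PrE")
    outputs <- c(features = write_tsv_table(feats,
                                            file.path(out, "features.tsv")),
                 roc = write_tsv_table(roc$points,
                                       file.path(out, "roc_points.tsv")))
    summary <- list(auc = roc$auc, threshold = roc$threshold, j = roc$j)
  } else if (stage == "colonies") {
    img <- as.matrix(read_tsv_table(config$image))
    res <- count_colonies(
      img, blur_sigma = config$blur_sigma %||% 2,
      area_range = c(config$area_min %||% 50, config$area_max %||% Inf),
      circularity_range = c(config$circularity_min %||% 0.5,
                            config$circularity_max %||% 1.2))
    outputs <- c(components = write_tsv_table(
                   res$components, file.path(out, "components.tsv")))
    summary <- list(count = res$count)
  } else if (stage == "classify") {
    cells <- read_tsv_table(config$cells)
    thresholds <- unlist(config$thresholds)
    res <- classify_cells(cells, thresholds,
                          min_area = config$min_area %||% 40)
    outputs <- c(proportions = write_tsv_table(
                   res$proportions, file.path(out, "proportions.tsv")),
                 summary_tbl = write_tsv_table(
                   res$summary, file.path(out, "class_summary.tsv")))
    summary <- list(n_cells = nrow(res$cells))
  }

  manifest <- list(stage = stage,
                   parameters = config[setdiff(names(config),
                                               c("stage", "out_dir"))],
                   package_version = as.character(
                     utils::packageVersion("medsift")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs <- c(outputs, manifest = file.path(out, "manifest.json"),
               summary = file.path(out, "summary.json"))
  stage_log(stage, "done")
  invisible(list(outputs = outputs, summary = summary))
}
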