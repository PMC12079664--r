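test_that("screen generator is reproducible and validates its inputs", {
  tr <- screen_truth(n_genes = 30, n_controls = 20, depth = 1e4, seed = 7)
  a <- simulate_screen(tr)
  b <- simulate_screen(tr)
  expect_identical(a$counts, b$counts)
  expect_error(screen_truth(depth = 0), "depth")
  expect_error(screen_truth(gates = tibble::tibble(fraction = numeric(),
                                                   day = numeric())),
               "non-empty")
  expect_error(screen_truth(gates = tibble::tibble(fraction = 1.5, day = 6)),
               "0, 1")
  expect_error(screen_truth(effect = Inf), "finite")
})

test_that("null screen shows no differential enrichment of sorted gates", {
  tr <- screen_truth(n_genes = 200, n_controls = 200, effect = 0,
                     depth = 5e5, library_dispersion = 0.2, seed = 11,
                     gates = tibble::tibble(fraction = 0.05, day = 6,
                                            direction = "low"))
  ds <- simulate_screen(tr)
  norm <- total_count_normalize(ds$counts)
  stats <- guide_log2fc(norm, "low_5pct_d6")
  # targeting and control guides are exchangeable under the null
  summ <- control_enrichment_summary(stats)
  expect_lt(abs(summ$rank_sum$z), 3)
  expect_lt(abs(mean(stats$log2fc)), 0.05)
})

test_that("a strong negative effect enriches the gene's guides as the Gaussian tail predicts", {
  # oracle: P(cell in lowest-1% gate | effect mu) = pnorm(q01, mu, sd) with
  # q01 the population 1% quantile; for one affected gene among many nulls
  # q01 ~ qnorm(0.01) and the expected frequency ratio sorted/unsorted is
  # pnorm(q01, -3, 1) / 0.01 >> 1
  q01 <- qnorm(0.01)
  oracle_ratio <- pnorm(q01, mean = -3, sd = 1) / 0.01
  expect_gt(oracle_ratio, 10)
  for (seed in 1:3) {
    tr <- screen_truth(n_genes = 50, n_controls = 50,
                       effect = c(-3, rep(0, 49)), depth = 1e6,
                       library_dispersion = 0, seed = seed,
                       gates = tibble::tibble(fraction = 0.01, day = 6,
                                              direction = "low"))
    ds <- simulate_screen(tr)
    hit <- ds$counts$gene %in% "gene0001"
    f_sorted <- sum(ds$counts$low_1pct_d6[hit]) / sum(ds$counts$low_1pct_d6)
    f_ref <- sum(ds$counts$unsorted[hit]) / sum(ds$counts$unsorted)
    expect_gt(f_sorted, f_ref)          # joint over-representation
    expect_gt(f_sorted / f_ref, oracle_ratio * 0.5)
  }
})

test_that("reference time course has the analytic sigmoid half-time property", {
  ref <- simulate_reference_timecourse(markers = c("m1", "m2"), t_max_h = 96,
                                       step_h = 0.1, rates = c(1 / 24, 2 / 24),
                                       initial = 8, floor = 2)
  expect_equal(ref$m1[ref$time_h == 0], 8)
  half_time <- function(v, t, init, fl) {
    target <- fl + (init - fl) / 2
    approx(v, t, xout = target)$y
  }
  t1 <- half_time(ref$m1, ref$time_h, 8, 2)
  t2 <- half_time(ref$m2, ref$time_h, 8, 2)
  expect_equal(t1, 24, tolerance = 0.01)
  expect_equal(t2, t1 / 2, tolerance = 0.01)
  # rate 0 -> constant profile; negative rates rejected
  flat <- simulate_reference_timecourse(markers = "m", rates = 0)
  expect_true(all(flat$m == flat$m[1]))
  expect_error(simulate_reference_timecourse(markers = "m", rates = -1),
               "rates")
})

test_that("bulk generator satisfies its construction identities", {
  ref <- simulate_reference_timecourse(step_h = 0.5)
  # identity case: c = 1, no delay, no noise -> genotypes indistinguishable
  be0 <- simulate_bulk_expression(
    expression_truth(attenuation = 1, delay_h = 0, noise_sd = 0, seed = 3),
    ref, n_background = 50)
  expect_equal(be0$wt_fc$log2fc, be0$mut_fc$log2fc, tolerance = 1e-12)
  wt_vals <- dplyr::filter(be0$expression, genotype == "wt")$tpm
  mut_vals <- dplyr::filter(be0$expression, genotype == "mutant")$tpm
  expect_equal(wt_vals, mut_vals, tolerance = 1e-12)
  # attenuation c = 0.5 -> exact ratio 0.5 per non-marker gene at zero noise
  be <- simulate_bulk_expression(
    expression_truth(attenuation = 0.5, delay_h = 0, noise_sd = 0, seed = 3),
    ref, n_background = 50)
  nonmark <- setdiff(be$wt_fc$gene, be$markers)
  wt <- be$wt_fc$log2fc[match(nonmark, be$wt_fc$gene)]
  mut <- be$mut_fc$log2fc[match(nonmark, be$mut_fc$gene)]
  expect_equal(mut, 0.5 * wt, tolerance = 1e-12)
  # planted delay 6 h -> mutant marker vector equals the reference at 18 h
  bed <- simulate_bulk_expression(
    expression_truth(attenuation = 1, delay_h = 6, noise_sd = 0, seed = 3),
    ref, n_background = 10)
  mut24 <- bed$expression %>%
    dplyr::filter(genotype == "mutant", condition == "N2B27_24h",
                  gene %in% bed$markers, replicate == 1)
  ref18 <- medsift:::reference_at(ref, 18)[1, bed$markers]
  expect_equal(unname(log2(mut24$tpm[match(bed$markers, mut24$gene)])),
               unname(ref18), tolerance = 1e-12)
  expect_error(expression_truth(attenuation = 0), "attenuation")
})

test_that("bulk generator rejects footprint sets overlapping the marker panel", {
  ref <- simulate_reference_timecourse(step_h = 2)
  fp <- tibble::tibble(pathway = "P", gene = c("Nanog", "x1", "x2"),
                       delta = c(1, 1, 1))
  expect_error(simulate_bulk_expression(expression_truth(seed = 1), ref,
                                        footprints = fp),
               "overlap")
})

test_that("trace generator labels fates by strict peak threshold and reproduces", {
  tt <- trace_truth(n_cells = 40, true_threshold = 1, noise_sd = 0, seed = 5)
  ts1 <- simulate_traces(tt)
  ts2 <- simulate_traces(tt)
  expect_identical(ts1$traces, ts2$traces)
  expect_setequal(unique(ts1$cells$fate), c("PrE", "other"))
  # noise-free labels perfectly separable by the peak
  feats <- trace_feature(ts1$traces)
  roc <- roc_youden(feats$value, feats$fate)
  expect_equal(roc$auc, 1)
  # strict inequality at the boundary
  expect_true(all(ts1$cells$fate[ts1$cells$peak <= 1] == "other"))
  expect_error(trace_truth(n_cells = 1), "n_cells")
})

test_that("mixture generator is exchangeable in component order and separable", {
  a <- simulate_mixture(100, means = c(2, 4), sds = c(0.3, 0.2), seed = 9)
  b <- simulate_mixture(100, means = c(4, 2), sds = c(0.2, 0.3), seed = 9)
  expect_identical(a, b)
  expect_error(simulate_mixture(100, means = c(2, 2), sds = c(0.3, 0.3)),
               "distinct")
  # 10-sd separation: misassignment by the fitted model is essentially zero
  big <- simulate_mixture(500, means = c(2, 5), sds = c(0.3, 0.3), seed = 2)
  fit <- gmm_assign(big$intensity)
  assigned <- !is.na(fit$cells$component)
  expect_true(all(fit$cells$component[assigned] == big$component[assigned]))
})

test_that("colony image generator plants non-overlapping colonies with known shape", {
  ci <- simulate_colony_image(5, radius_range = c(8, 12), noise_sd = 0,
                              seed = 4)
  expect_equal(nrow(ci$truth), 5)
  # zero-noise disks are 5 distinct bright components
  lab <- EBImage::bwlabel(EBImage::Image((ci$image > 0.5) * 1))
  expect_equal(max(lab), 5)
  # ellipse with axis ratio 4 has circularity < 0.6 (Ramanujan perimeter)
  ce <- simulate_colony_image(1, radius_range = c(10, 10), axis_ratio = 4,
                              noise_sd = 0, seed = 1)
  expect_lt(ce$truth$circularity, 0.6)
  # empty image
  c0 <- simulate_colony_image(0, seed = 1)
  expect_equal(nrow(c0$truth), 0)
  # impossible placement errors out
  expect_error(simulate_colony_image(500, radius_range = c(20, 30),
                                     image_size = c(128, 128), seed = 1),
               "could not place")
})
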