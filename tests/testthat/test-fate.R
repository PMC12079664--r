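make_trace <- function(intensity, cell_id = "c1") {
  tibble::tibble(cell_id = cell_id, frame = seq_along(intensity),
                 time_min = (seq_along(intensity) - 1) * 10,
                 intensity = intensity, fate = "other")
}

test_that("rolling smoothing has the stated convolution behaviour", {
  const <- make_trace(rep(3, 20))
  expect_equal(smooth_trace(const)$intensity, rep(3, 20))
  # interior impulse of height 7 -> plateau of 1 across 7 frames
  imp <- make_trace(c(rep(0, 9), 7, rep(0, 9)))
  sm <- smooth_trace(imp)
  expect_equal(sm$intensity[7:13], rep(1, 7))
  expect_equal(sm$intensity[c(1:6, 14:19)], rep(0, 12))
  # window = 1 is the identity
  noisy <- make_trace(rnorm(15))
  expect_equal(smooth_trace(noisy, window = 1)$intensity, noisy$intensity)
  expect_error(smooth_trace(make_trace(1:5)), "shorter")
  expect_error(smooth_trace(noisy, window = 4), "odd")
})

test_that("trace features summarise smoothed traces", {
  rising <- make_trace(1:20)
  expect_equal(trace_feature(rising, "peak")$value, 20)
  expect_equal(trace_feature(rising, "end_of_induction")$value, 20)
  bump <- make_trace(c(1:10, 9:1))
  expect_equal(trace_feature(bump, "peak")$value, 10)
  expect_error(trace_feature(bump, "nope"), "unknown feature")
  # smoothing can only lower the peak
  set.seed(2)
  tr <- make_trace(abs(rnorm(30)))
  expect_lte(trace_feature(smooth_trace(tr))$value,
             trace_feature(tr)$value)
})

test_that("ROC analysis: AUC equals the rank-sum statistic and brute-force Youden", {
  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    x <- c(rnorm(n1, 1), rnorm(n2))
    labs <- rep(c("PrE", "other"), c(n1, n2))
    roc <- roc_youden(x, labs)
    u <- unname(wilcox.test(x[labs == "PrE"], x[labs == "other"],
                            exact = FALSE)$statistic)
    expect_equal(roc$auc, u / (n1 * n2), tolerance = 1e-12)
    # brute-force maximization over every candidate threshold
    cand <- c(-Inf, sort(unique(x)))
    j_brute <- vapply(cand, function(t) {
      sens <- mean(x[labs == "PrE"] > t)
      spec <- mean(x[labs == "other"] <= t)
      sens + spec - 1
    }, numeric(1))
    expect_equal(roc$j, max(j_brute), tolerance = 1e-12)
    expect_equal(roc$threshold, min(cand[j_brute == max(j_brute)]))
  }
})

test_that("ROC handles separable, null and degenerate inputs", {
  x <- c(1, 2, 3, 11, 12, 13)
  labs <- rep(c("other", "PrE"), each = 3)
  roc <- roc_youden(x, labs)
  expect_equal(roc$auc, 1)
  expect_equal(roc$j, 1)
  expect_gte(roc$threshold, 3)
  expect_lt(roc$threshold, 11)
  # permuted labels -> AUC near 1/2
  set.seed(7)
  xr <- rnorm(400)
  lr <- sample(rep(c("PrE", "other"), 200))
  expect_lt(abs(roc_youden(xr, lr)$auc - 0.5), 0.1)
  expect_error(roc_youden(x, rep("PrE", 6)), "both classes")
})

test_that("recovered Youden threshold tracks the planted trace threshold", {
  for (seed in 1:5) {
    tt <- trace_truth(n_cells = 120, true_threshold = 1, noise_sd = 0.05,
                      seed = seed)
    feats <- simulate_traces(tt) |> smooth_trace() |> trace_feature()
    roc <- roc_youden(feats$value, feats$fate)
    expect_lt(abs(roc$threshold - tt$true_threshold), 2 * tt$noise_sd)
  }
})

test_that("EM mixture fit recovers parameters and honours the posterior rule", {
  mix <- simulate_mixture(1000, means = c(2, 3), sds = c(0.25, 0.25),
                          seed = 3)
  fit <- gmm_assign(mix$intensity)
  expect_equal(fit$components$mean_log10, c(2, 3), tolerance = 0.05)
  expect_equal(fit$components$sd_log10, c(0.25, 0.25), tolerance = 0.05)
  # posteriors sum to one; assignment only at >= 0.85
  expect_equal(fit$cells$posterior_1 + fit$cells$posterior_2,
               rep(1, nrow(fit$cells)))
  assigned <- !is.na(fit$cells$component)
  expect_true(all(pmax(fit$cells$posterior_1,
                       fit$cells$posterior_2)[assigned] >= 0.85))
  expect_true(all(pmax(fit$cells$posterior_1,
                       fit$cells$posterior_2)[!assigned] < 0.85))
  # order invariance and canonical component order
  perm <- sample(nrow(mix))
  fit2 <- gmm_assign(mix$intensity[perm])
  expect_equal(fit2$components, fit$components, tolerance = 1e-9)
  expect_equal(fit2$cells$component, fit$cells$component[perm])
  expect_error(gmm_assign(rep(10, 5)), ">= 20")
})

test_that("a cell exactly midway between equal components stays unassigned", {
  # symmetric sample: the fitted mixture is symmetric about the midpoint,
  # so the midpoint cell has posterior 1/2 for each component
  base <- c(rnorm(500, 2, 0.2), rnorm(500, 4, 0.2))
  sym <- c(base, 2 + 4 - base)     # enforce exact symmetry about 3
  x <- 10^c(sym, 3)
  fit <- gmm_assign(x)
  mid_post <- fit$cells$posterior_1[length(x)]
  expect_equal(mid_post, 0.5, tolerance = 0.02)
  expect_true(is.na(fit$cells$component[length(x)]))
})

test_that("misassignment among assigned cells matches the Gaussian overlap oracle", {
  sep <- 3; sd0 <- 0.3
  mix <- simulate_mixture(3000, means = c(2, 2 + sep * sd0),
                          sds = c(sd0, sd0), seed = 8)
  fit <- gmm_assign(mix$intensity)
  cells <- fit$cells
  assigned <- !is.na(cells$component)
  mis <- mean(cells$component[assigned] != mix$component[assigned])
  # oracle from the true parameters: equal weights/sds, the 0.85 posterior
  # band excludes x within (log(0.85/0.15)/sep)*sd0 of the midpoint
  m <- 2 + sep * sd0 / 2
  band <- log(0.85 / 0.15) * sd0 / sep
  p_wrong <- pnorm(m + band, 2, sd0, lower.tail = FALSE)
  p_assigned <- pnorm(m - band, 2, sd0) + p_wrong
  oracle <- p_wrong / p_assigned
  se <- sqrt(oracle * (1 - oracle) / sum(assigned))
  expect_lt(abs(mis - oracle), 3 * se + 0.002)
})
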