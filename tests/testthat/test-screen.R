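test_that("total-count normalization rescales every sample to the mean total", {
  tab <- tibble::tibble(guide_id = c("a", "b"), gene = c("g1", "g2"),
                        is_control = FALSE,
                        s1 = c(60, 40), s2 = c(100, 200))
  norm <- total_count_normalize(tab, sample_cols = c("s1", "s2"))
  expect_equal(sum(norm$s1), 200)  # mean of totals 100 and 300
  expect_equal(sum(norm$s2), 200)
  # already-equal totals and single sample are unchanged
  expect_equal(total_count_normalize(tab["s1"], "s1")$s1, tab$s1)
  eq <- tibble::tibble(s1 = c(1, 2), s2 = c(2, 1))
  expect_equal(total_count_normalize(eq), eq)
  bad <- tibble::tibble(guide_id = "a", s1 = 1, s2 = 0)
  expect_error(total_count_normalize(bad, c("s1", "s2")), "s2")
})

test_that("guide log2 fold change follows the pseudocounted closed form", {
  tab <- tibble::tibble(guide_id = c("g1", "g2", "g3"),
                        gene = c("A", "A", "B"), is_control = FALSE,
                        sorted = c(31, 7, 7), unsorted = c(7, 7, 31))
  st <- guide_log2fc(tab, "sorted", "unsorted")
  expect_equal(st$log2fc[st$guide_id == "g1"], 2)      # log2(32/8)
  expect_equal(st$log2fc[st$guide_id == "g2"], 0)
  expect_equal(st$rank[st$guide_id == "g1"], 1L)       # most enriched
  expect_equal(st$percentile[st$guide_id == "g1"], 1 / 3)
  expect_true(all(sort(st$rank) == 1:3))
  # sorted = reference -> all zero
  same <- guide_log2fc(dplyr::mutate(tab, sorted = unsorted),
                       "sorted", "unsorted")
  expect_true(all(same$log2fc == 0))
  expect_error(guide_log2fc(dplyr::bind_rows(tab, tab), "sorted", "unsorted"),
               "duplicated")
})

test_that("alpha-RRA rho matches closed-form order-statistic probabilities", {
  st <- make_guide_stats(c(0.1, 0.3))
  # beta_1 = 1 - 0.9^2 = 0.19, beta_2 = 0.3^2 = 0.09
  expect_equal(alpha_rra_score(st, alpha = 1)$rho, 0.09, tolerance = 1e-12)
  # truncation: alpha = 0.2 keeps only k = 1
  expect_equal(alpha_rra_score(st, alpha = 0.2)$rho, 0.19, tolerance = 1e-12)
  # worst case: no participating guide
  expect_equal(alpha_rra_score(make_guide_stats(c(1, 1)), alpha = 0.5)$rho, 1)
})

test_that("rho is monotone and invariant to guide order within a gene", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    u <- sort(runif(n))
    alpha <- runif(1, 0.1, 1)
    rho <- medsift:::rra_rho(u, alpha)
    expect_gte(rho, 0); expect_lte(rho, 1)
    # improving any participating percentile never increases rho
    k <- sample(seq_len(n), 1)
    u2 <- u; u2[k] <- u2[k] * runif(1)
    expect_lte(medsift:::rra_rho(sort(u2), alpha), rho + 1e-14)
    # order invariance
    expect_equal(medsift:::rra_rho(sample(u), alpha), rho)
  }
})

test_that("permutation p-values match exhaustive enumeration on a tiny library", {
  # 8 guides total, one gene with 4 of them: exhaustive null over C(8,4)
  u_all <- c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 1)
  gene_u <- u_all[c(1, 2, 3, 6)]
  alpha <- 0.6
  rho_obs <- medsift:::rra_rho(gene_u, alpha)
  combs <- utils::combn(8, 4)
  rho_null <- apply(combs, 2, function(ix) medsift:::rra_rho(u_all[ix], alpha))
  p_exact <- mean(rho_null <= rho_obs)

  stats <- tibble::tibble(
    guide_id = sprintf("sg%d", 1:8),
    gene = c("A", "A", "A", NA, NA, "A", NA, NA),
    is_control = is.na(gene), log2fc = -u_all,
    rank = 1:8, percentile = u_all)
  n_perm <- 2000
  res <- permutation_fdr(stats, alpha = alpha, n_perm = n_perm, seed = 10)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_perm - p_exact), 2 * mc_se + 1 / (n_perm + 1))
})

test_that("a gene holding the best-ranked guides gets the minimal p-value", {
  u_all <- (1:20) / 20
  stats <- tibble::tibble(
    guide_id = sprintf("sg%02d", 1:20),
    gene = c(rep("top", 4), rep(NA, 16)),
    is_control = is.na(gene), log2fc = -u_all, rank = 1:20,
    percentile = u_all)
  res <- permutation_fdr(stats, alpha = 1, n_perm = 500, seed = 2)
  expect_equal(res$p_perm, 1 / 501, tolerance = 1e-12)
})

test_that("null permutation p-values are approximately uniform", {
  # 200 null genes of 4 guides each: KS distance below the 1% critical value
  set.seed(3)
  n_genes <- 200
  u_all <- sample(seq_len(4 * n_genes)) / (4 * n_genes)
  stats <- tibble::tibble(
    guide_id = sprintf("sg%04d", seq_along(u_all)),
    gene = rep(sprintf("g%03d", seq_len(n_genes)), each = 4),
    is_control = FALSE, log2fc = -u_all,
    rank = rank(u_all), percentile = u_all)
  res <- permutation_fdr(stats, alpha = 1, n_perm = 500, seed = 4)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))$statistic
  expect_lt(unname(ks), 1.63 / sqrt(n_genes))  # 1% critical value
})

test_that("alphamean gene LFC filters by percentile with a documented fallback", {
  st <- tibble::tibble(guide_id = c("a", "b"), gene = "G", is_control = FALSE,
                       log2fc = c(2, 0), rank = 1:2,
                       percentile = c(0.1, 0.9))
  expect_equal(gene_lfc_alphamean(st, alpha = 0.5)$lfc_alphamean, 2)
  expect_equal(gene_lfc_alphamean(st, alpha = 1)$lfc_alphamean, 1)
  # no guide passes: fall back to the mean of all guides
  st2 <- dplyr::mutate(st, log2fc = c(1, 3), percentile = c(0.8, 0.9))
  expect_equal(gene_lfc_alphamean(st2, alpha = 0.5)$lfc_alphamean, 2)
})

test_that("compound hit rule implements primary-or-two-secondary selection", {
  mk <- function(fdrs) {
    purrr::imap(fdrs, function(f, i) tibble::tibble(gene = "G", fdr = f))
  }
  hit1 <- select_hits(mk(list(0.01, 0.9, 0.9, 0.9)))
  expect_true(hit1$is_hit)                       # primary clause
  hit2 <- select_hits(mk(list(0.15, 0.18, 0.9, 0.9)))
  expect_true(hit2$is_hit)                       # two-secondary clause
  hit3 <- select_hits(mk(list(0.15, 0.9, 0.9, 0.9)))
  expect_false(hit3$is_hit)                      # complement
  # missing gene-condition entries count as FDR = 1
  tabs <- list(c1 = tibble::tibble(gene = c("A", "B"), fdr = c(0.01, 0.3)),
               c2 = tibble::tibble(gene = "A", fdr = 0.1))
  h <- select_hits(tabs)
  expect_equal(h$fdr_c2[h$gene == "B"], 1)
  expect_true(h$is_hit[h$gene == "A"])
  expect_false(h$is_hit[h$gene == "B"])
  expect_error(select_hits(list()), "non-empty")
})

test_that("control enrichment summary matches exact rank-sum enumeration", {
  st <- tibble::tibble(guide_id = sprintf("s%d", 1:5),
                       gene = c("A", "A", NA, NA, NA),
                       is_control = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                       log2fc = c(3, 4, 1, 2, 0.5),
                       rank = c(2, 1, 4, 3, 5),
                       percentile = c(2, 1, 4, 3, 5) / 5)
  res <- control_enrichment_summary(st)
  # W = number of (targeting, control) pairs with targeting > control = 6
  expect_equal(res$rank_sum$statistic, 6)
  expect_gt(res$rank_sum$z, 0)
  # identical distributions -> z = 0
  same <- tibble::tibble(guide_id = sprintf("s%d", 1:4),
                         gene = c("A", "A", NA, NA),
                         is_control = c(FALSE, FALSE, TRUE, TRUE),
                         log2fc = c(1, 2, 1, 2), rank = 1:4,
                         percentile = (1:4) / 4)
  expect_equal(control_enrichment_summary(same)$rank_sum$z, 0)
  only_t <- dplyr::mutate(st, is_control = FALSE)
  expect_error(control_enrichment_summary(only_t), "both")
})
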