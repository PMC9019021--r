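test_that("top_n_by_cleavage selects highest scores with genomic tie-break", {
  g <- test_genome(1e6)
  sc <- withr::with_seed(1, stats::runif(100))
  sites <- test_sites(seq(5000, 500000, by = 5000), g, cleavage = sc)
  top <- top_n_by_cleavage(sites, 80)
  expect_length(top, 80)
  expect_setequal(S4Vectors::mcols(top)$site_id,
                  sprintf("DSB_%03d", order(-sc)[1:80]))  # sort-and-slice
  expect_identical(top_n_by_cleavage(sites, 100), sites)
  expect_error(top_n_by_cleavage(sites, 101), "exceeds")
})

test_that("ratio_classify labels n_extreme sites per class", {
  g <- test_genome(1e6)
  sites <- test_sites(seq(10000, 800000, by = 10000), g)  # 80 sites
  n <- length(sites)
  fac <- rep(1, 10000); cle <- rep(1, 10000)
  # plant 5x factor signal at sites 1..20 (factor window bins)
  for (p in GenomicRanges::start(sites)[1:20]) {
    i <- (p - 1) %/% 100 + 1
    fac[i] <- 5
  }
  ftr <- signal_track(list(sim1 = fac), 100, g, total_reads = sum(fac))
  ctr <- signal_track(list(sim1 = cle), 100, g, total_reads = sum(cle))
  cls <- ratio_classify(sites, ftr, ctr, n_extreme = 20)
  expect_equal(sum(cls$label == "high"), 20)
  expect_equal(sum(cls$label == "low"), 20)
  expect_equal(which(cls$label == "high"), 1:20)

  # n_extreme = n/2 partitions all sites
  cls2 <- ratio_classify(sites, ftr, ctr, n_extreme = 40)
  expect_equal(sort(unique(cls2$label)), c("high", "low"))

  # all-identical signal: degenerate, labels by genomic order
  expect_warning(cls3 <- ratio_classify(sites, ctr, ctr, n_extreme = 20),
                 "tie rule")
  expect_true(attr(cls3, "degenerate"))
  expect_equal(which(cls3$label == "high"), 1:20)

  zero <- signal_track(list(sim1 = rep(0, 10000)), 100, g, total_reads = 1)
  expect_error(ratio_classify(sites, ftr, zero, pseudocount = 0),
               "pseudocount")
  expect_error(ratio_classify(sites, ftr, ctr, n_extreme = 41), "n_extreme")
})

test_that("ratio_classify recovers planted high-recruitment sites", {
  recovered <- vapply(1:3, planted_ratio_run, numeric(1))
  expect_true(all(recovered >= 18))
})

test_that("quantile_groups splits by the remainder rule", {
  g <- test_genome(1e6)
  sites80 <- test_sites(seq(1e4, 8e5, by = 1e4), g)
  sc <- withr::with_seed(2, stats::runif(80))
  grp <- quantile_groups(sites80, sc, 4)
  expect_equal(as.integer(table(grp$group)), c(20, 20, 20, 20))
  expect_equal(attr(grp, "group_levels"),
               c("high", "medium_high", "medium_low", "low"))
  means <- tapply(grp$score, grp$group, mean)
  expect_true(all(diff(means) < 0))  # monotone by construction

  sites10 <- test_sites(seq(1e4, 1e5, by = 1e4), g)
  grp10 <- quantile_groups(sites10, stats::runif(10), 4)
  expect_equal(as.integer(table(grp10$group)), c(3, 3, 2, 2))
})

test_that("classification is invariant to input order up to the genomic tie rule", {
  g <- test_genome(1e6)
  sc <- withr::with_seed(3, stats::runif(40))
  pos <- seq(2e4, 8e5, length.out = 40)
  sites <- test_sites(pos, g, cleavage = sc)
  perm <- withr::with_seed(4, sample(40))
  shuffled <- sites[perm]
  grp1 <- quantile_groups(sites, sc, 4)
  grp2 <- quantile_groups(shuffled, sc[perm], 4)
  m1 <- setNames(grp1$group, grp1$site_id)
  m2 <- setNames(grp2$group, grp2$site_id)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("wilcoxon_ranksum matches exact enumeration and known cases", {
  res <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$mode_used, "exact")
  expect_equal(res$p_value, 0.1)
  expect_equal(unname(res$statistic), 0)

  same <- wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # enumeration oracle over random tie-free inputs, all sizes <= 5
  set.seed(42)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- sample(1000, n1 + n2) / 7
    a <- x[1:n1]; b <- x[-(1:n1)]
    expect_equal(wilcoxon_ranksum(a, b, mode = "exact")$p_value,
                 oracle_wilcox_p(a, b), tolerance = 1e-12)
  }

  # exact and normal approximation agree closely at n = 6 + 6
  set.seed(7)
  x <- rnorm(12)
  pe <- wilcoxon_ranksum(x[1:6], x[7:12], mode = "exact")$p_value
  pn <- wilcoxon_ranksum(x[1:6], x[7:12], mode = "normal_approx")$p_value
  expect_lt(abs(pe - pn), 0.05)

  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "empty")
  expect_error(wilcoxon_ranksum(c(1, 1, 2), c(2, 3, 4), mode = "exact"),
               "ties")
})

test_that("top transcription group dominates in a coupled simulation", {
  g <- genome_spec(c(sim1 = 1e7))
  sites <- top_n_by_cleavage(make_sites(g, 100, 50000, seed = 5), 80)
  # factor amplitude proportional to transcription^1, planted >= 3x contrast
  reads <- simulate_reads(sites, kernel_resection_early(),
                          total_reads = 2e5, seed = 6)
  fac <- window_sum(cpm_normalize(coverage_track(reads, 100)), sites, 5000)
  grp <- quantile_groups(sites,
                         S4Vectors::mcols(sites)$transcription_score, 4)
  cmp <- wilcoxon_ranksum(fac[grp$group == 1], fac[grp$group == 4])
  expect_lt(cmp$p_value, 0.01)
  expect_gt(median(fac[grp$group == 1]), median(fac[grp$group == 4]))
})

test_that("boxplot_stats applies interpolated quartiles and the 1.5 IQR rule", {
  s <- boxplot_stats(1:9)
  expect_equal(s$median, 5); expect_equal(s$q1, 3); expect_equal(s$q3, 7)
  expect_length(s$outliers, 0)
  expect_equal(s$whisker_low, 1); expect_equal(s$whisker_high, 9)

  s2 <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(s2$q1, 2); expect_equal(s2$q3, 4)
  expect_equal(s2$outliers, 100)  # fence at 4 + 1.5*2 = 7
  expect_equal(s2$whisker_high, 4)

  s3 <- boxplot_stats(3.5)
  expect_equal(s3$median, 3.5)
  expect_equal(s3$q1, 3.5); expect_equal(s3$q3, 3.5)
  expect_equal(s3$whisker_low, 3.5); expect_equal(s3$whisker_high, 3.5)
})
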