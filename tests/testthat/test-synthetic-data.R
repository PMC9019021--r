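test_that("make_sites respects packing constraints and is deterministic", {
  g <- genome_spec(c(sim1 = 1e7))
  sites <- make_sites(g, n_sites = 80, min_gap = 50000, seed = 1)
  expect_length(sites, 80)
  expect_true(all(diff(GenomicRanges::start(sites)) >= 50000))
  expect_true(all(GenomicRanges::start(sites) >= 1 &
                  GenomicRanges::start(sites) <= 1e7))
  # cleavage grades are distinct (top-N always well defined)
  expect_equal(anyDuplicated(S4Vectors::mcols(sites)$cleavage_score), 0L)
  expect_true(all(S4Vectors::mcols(sites)$transcription_score > 0))

  again <- make_sites(g, n_sites = 80, min_gap = 50000, seed = 1)
  expect_identical(GenomicRanges::start(sites), GenomicRanges::start(again))
  expect_identical(S4Vectors::mcols(sites), S4Vectors::mcols(again))
  other <- make_sites(g, n_sites = 80, min_gap = 50000, seed = 2)
  expect_false(identical(GenomicRanges::start(sites),
                         GenomicRanges::start(other)))

  expect_error(make_sites(genome_spec(c(sim1 = 1e5)), 80, 50000, seed = 1),
               "infeasible")
})

test_that("make_sites spreads sites over multiple contigs", {
  g <- genome_spec(c(a = 6e6, b = 4e6))
  sites <- make_sites(g, 100, 10000, seed = 3)
  tab <- table(as.character(GenomicRanges::seqnames(sites)))
  expect_equal(as.integer(tab[c("a", "b")]), c(60, 40))
})

test_that("simulate_reads conserves counts and respects kernel support", {
  g <- test_genome(1e6)
  sites <- test_sites(c(2e5, 5e5, 8e5), g)
  reads <- simulate_reads(sites, kernel_cleavage(), background_rate = 0,
                          total_reads = 5000, read_len = 50, seed = 1)
  expect_length(reads, 5000)
  # point kernel, no background: every read starts at a site
  expect_true(all(GenomicRanges::start(reads) %in%
                  GenomicRanges::start(sites)))
  expect_true(S4Vectors::isSorted(GenomicRanges::start(reads)))

  again <- simulate_reads(sites, kernel_cleavage(), background_rate = 0,
                          total_reads = 5000, read_len = 50, seed = 1)
  expect_identical(GenomicRanges::start(reads), GenomicRanges::start(again))
})

test_that("exponential kernel offsets have the planted decay length", {
  g <- test_genome(1e7)
  sites <- test_sites(5e6, g)
  kern <- factor_kernel("exponential", decay_length_bp = 2000, amplitude = 1)
  reads <- simulate_reads(sites, kern, background_rate = 0,
                          total_reads = 1e5, read_len = 50, seed = 7)
  d <- abs(GenomicRanges::start(reads) - 5e6)
  se <- 2000 / sqrt(1e5)
  expect_lt(abs(mean(d) - 2000), 3 * se + 0.5)  # +0.5 for integer rounding
})

test_that("background-only reads are Poisson-uniform across bins", {
  g <- test_genome(1e6)
  sites <- test_sites(5e5, g, cleavage = 1)
  kern <- factor_kernel("point", amplitude = 0)
  reads <- simulate_reads(sites, kern, background_rate = 1e-3,
                          total_reads = 2e4, read_len = 50, seed = 11)
  counts <- coverage_track(reads, bin_size = 1e4)$values[[1]]
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 1e-3)
})

test_that("plateau_with_dip kernel is bounded and depleted at the center", {
  g <- test_genome(1e6)
  sites <- test_sites(5e5, g, cleavage = 1)
  kern <- factor_kernel("plateau_with_dip", plateau_halfwidth_bp = 10000,
                        dip_halfwidth_bp = 2000, dip_depth = 0.2)
  reads <- simulate_reads(sites, kern, background_rate = 0,
                          total_reads = 5e4, read_len = 50, seed = 5)
  off <- GenomicRanges::start(reads) - 5e5
  expect_true(all(abs(off) <= 10000))
  dens_dip <- sum(abs(off) < 2000) / 4000
  dens_plat <- sum(abs(off) >= 2000) / 16000
  expect_lt(dens_dip, 0.5 * dens_plat)
})

test_that("correlated tracks plant the requested per-site correlation", {
  g <- genome_spec(c(sim1 = 1e7))
  sites <- top_n_by_cleavage(make_sites(g, 100, 50000, seed = 1), 80)

  tr <- simulate_correlated_tracks(sites, kernel_resection_early(),
                                   target_pearson = 1, seed = 2)
  a <- tr$amplitudes
  expect_equal(a$a1, a$a2, tolerance = 1e-12)

  r08 <- vapply(1:4, function(s) {
    tr <- simulate_correlated_tracks(sites, kernel_resection_early(),
                                     target_pearson = 0.8, seed = s)
    s1 <- window_sum(cpm_normalize(coverage_track(tr$track1, 100)),
                     sites, 10000)
    s2 <- window_sum(cpm_normalize(coverage_track(tr$track2, 100)),
                     sites, 10000)
    pearson_cor(s1, s2)
  }, numeric(1))
  expect_true(all(r08 > 0.6 & r08 < 0.95))

  tr0 <- simulate_correlated_tracks(sites, kernel_resection_early(),
                                    target_pearson = 0, seed = 3)
  r0 <- pearson_cor(tr0$amplitudes$a1, tr0$amplitudes$a2)
  expect_lt(abs(atanh(r0)), 1.96 / sqrt(80 - 3))  # Fisher-z null interval

  expect_error(simulate_correlated_tracks(sites, kernel_resection_early(),
                                          target_pearson = 1.2, seed = 1),
               "target_pearson")
})

test_that("simulate_qpcr follows the amplification model", {
  tab <- simulate_qpcr(1, efficiency = 2, ct_at_unit = 30, noise_sd = 0)
  expect_equal(tab$ct, 30)
  tab2 <- simulate_qpcr(c(1, 2), efficiency = 2, ct_at_unit = 30,
                        noise_sd = 0)
  expect_equal(tab2$ct[1] - tab2$ct[2], 1)  # doubling lowers Ct by one cycle

  noisy <- simulate_qpcr(rep(1, 1000), noise_sd = 0.2, seed = 4)
  expect_lt(abs(sd(noisy$ct) - 0.2), 0.02)

  expect_error(simulate_qpcr(c(1, -1)), "positive")
  expect_error(simulate_qpcr(1, efficiency = 2.5), "efficiency")
})

test_that("simulate_donors plants the NB interaction model", {
  d <- simulate_donors(2000, beta = c(log(5), 0, 0, 0), dispersion = Inf,
                       seed = 1)
  expect_lt(abs(mean(d$truth$td_count) - 5), 3 * sqrt(5 / 2000))
  # Poisson-like: variance close to mean
  expect_lt(var(d$truth$td_count) / mean(d$truth$td_count), 1.2)

  beta <- c(log(5), log(1.5), log(1.2), log(2))
  d2 <- simulate_donors(4000, beta = beta, dispersion = 2, seed = 2)
  with_both <- d2$truth$A == 1 & d2$truth$B == 1
  neither <- d2$truth$A == 0 & d2$truth$B == 0
  ratio <- mean(d2$truth$td_count[with_both]) /
    mean(d2$truth$td_count[neither])
  expect_lt(abs(log(ratio) - sum(beta[2:4])), 0.25)

  # SV table holds exactly the planted small TDs plus decoys
  cnt <- count_td(d2$sv, donors = d2$truth$donor_id)
  expect_equal(cnt$td_count, d2$truth$td_count)

  expect_identical(simulate_donors(50, seed = 9),
                   simulate_donors(50, seed = 9))
  expect_error(simulate_donors(50, dispersion = 0), "dispersion")
})
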