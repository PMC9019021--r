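## shared in-code fixtures and independent oracles

test_genome <- function(len = 1e6, name = "sim1") {
  genome_spec(stats::setNames(len, name))
}

## hand-built site catalog with planted scores
test_sites <- function(pos, genome, cleavage = NULL, transcription = NULL) {
  gr <- GenomicRanges::GRanges(
    names(genome)[1], IRanges::IRanges(start = pos, width = 1),
    seqinfo = dsbscape:::as_seqinfo(genome))
  n <- length(pos)
  S4Vectors::mcols(gr)$site_id <- sprintf("DSB_%03d", seq_len(n))
  S4Vectors::mcols(gr)$cleavage_score <-
    if (is.null(cleavage)) rev(seq_len(n)) / n else cleavage
  S4Vectors::mcols(gr)$transcription_score <-
    if (is.null(transcription)) rep(1, n) else transcription
  gr
}

## hand-built reads at given start positions
test_reads <- function(starts, genome, width = 50, strand = "+") {
  GenomicRanges::GRanges(
    names(genome)[1],
    IRanges::IRanges(start = starts, width = width),
    strand = strand,
    seqinfo = dsbscape:::as_seqinfo(genome))
}

## brute-force per-position read-start histogram, then binned
oracle_coverage <- function(starts, genome_len, bin_size) {
  hist_pos <- tabulate(starts, nbins = genome_len)
  nb <- ceiling(genome_len / bin_size)
  vapply(seq_len(nb), function(i) {
    lo <- (i - 1) * bin_size + 1
    hi <- min(i * bin_size, genome_len)
    sum(hist_pos[lo:hi])
  }, numeric(1))
}

## brute-force windowed sum: loop all bins, test start-in-window
oracle_window_sum <- function(values, bin_size, pos, window) {
  p0 <- pos - 1
  s <- 0
  for (i in seq_along(values)) {
    b0 <- (i - 1) * bin_size
    if (b0 >= p0 - window / 2 && b0 < p0 + window / 2) s <- s + values[i]
  }
  s
}

## full-enumeration two-sided rank-sum p-value (no ties)
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2, function(i) u_stat(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

## simulate + classify helper used by classification recovery tests
planted_ratio_run <- function(seed, n_sites = 80, planted_n = 20, fold = 5,
                              total_reads = 2e5) {
  g <- genome_spec(c(sim1 = 1e7))
  sites <- top_n_by_cleavage(make_sites(g, 120, 50000, seed = seed), n_sites)
  planted <- withr::with_seed(seed + 10L, sort(sample(n_sites, planted_n)))
  w <- rep(1, n_sites)
  w[planted] <- fold
  fr <- simulate_reads(sites, kernel_resection_early(),
                       total_reads = total_reads, seed = seed + 1L,
                       site_weights =
                         w * S4Vectors::mcols(sites)$cleavage_score)
  cr <- simulate_reads(sites, kernel_cleavage(),
                       total_reads = total_reads, seed = seed + 2L)
  cls <- ratio_classify(sites,
                        cpm_normalize(coverage_track(fr, 100)),
                        cpm_normalize(coverage_track(cr, 100)),
                        n_extreme = planted_n)
  sum(cls$label == "high" & seq_len(n_sites) %in% planted)
}
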