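test_that("read_reads parses BED and validates against the genome", {
  g <- test_genome(1000, "chr1")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t150\tr1\t0\t+", f)
  gr <- read_reads(f, "bed", g)
  expect_length(gr, 1)
  expect_equal(GenomicRanges::start(gr), 101)  # 0-based BED -> 1-based
  expect_equal(GenomicRanges::end(gr), 150)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")

  writeLines("chr1\t900\t2000\tr1\t0\t+", f)
  expect_error(read_reads(f, "bed", g), "contig end")
  writeLines("chrX\t10\t60\tr1\t0\t+", f)
  expect_error(read_reads(f, "bed", g), "chrX")

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_length(read_reads(empty, "bed", g), 0)
})

test_that("read_reads skips unmapped SAM records with a tally", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:10000",
               "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
               "r2\t16\tchr1\t201\t60\t50M\t*\t0\t0\t*\t*",
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), f)
  expect_message(gr <- read_reads(f, "sam"), "skipped 1 unmapped")
  expect_length(gr, 2)
  expect_equal(S4Vectors::metadata(gr)$skipped, 1L)
  expect_equal(GenomicRanges::start(gr), c(101, 201))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  expect_equal(unname(GenomeInfoDb::seqlengths(gr)), 10000)  # from @SQ
})

test_that("SAM writer round-trips simulated reads", {
  g <- test_genome(1e5)
  sites <- test_sites(5e4, g)
  reads <- simulate_reads(sites, kernel_resection_early(),
                          total_reads = 500, seed = 3)
  f <- withr::local_tempfile(fileext = ".sam")
  write_reads_sam(reads, f)
  back <- read_reads(f, "sam")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(reads))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(reads)))
})

test_that("deduplicate keeps one read per (contig, start, strand)", {
  g <- test_genome(1e5)
  r <- test_reads(c(100, 100, 100), g, strand = c("+", "+", "-"))
  dd <- deduplicate(r)
  expect_length(dd, 2)  # same start, opposite strands both survive
  expect_identical(deduplicate(dd), dd)  # idempotent

  # 1000 reads with 100 planted duplicates -> 900 survive (set oracle)
  starts <- withr::with_seed(1, sample(1e4, 900))
  dups <- withr::with_seed(2, sample(starts, 100))
  r2 <- test_reads(c(starts, dups), g)
  expect_length(deduplicate(r2), length(unique(c(starts, dups))))
  expect_length(deduplicate(r2), 900)
})

test_that("coverage_track counts read starts and conserves totals", {
  g <- test_genome(1000)
  r <- test_reads(c(101, 120, 150, 199, 105), g, width = 10)
  tr <- coverage_track(r, bin_size = 100)
  expect_equal(tr$values[[1]][2], 5)  # all five start in bin 2
  expect_equal(sum(tr$values[[1]]), 5)

  # random reads: bin=1 equals the per-position histogram oracle
  starts <- withr::with_seed(3, sample(1000 - 50, 500, replace = TRUE))
  r3 <- test_reads(starts, g)
  tr1 <- coverage_track(r3, bin_size = 1)
  expect_equal(tr1$values[[1]], oracle_coverage(starts, 1000, 1))
  # and any other bin size matches the binned oracle
  tr7 <- coverage_track(r3, bin_size = 77)
  expect_equal(tr7$values[[1]], oracle_coverage(starts, 1000, 77))
  expect_equal(sum(tr7$values[[1]]), 500)
})

test_that("cpm_normalize scales to counts per million exactly once", {
  g <- test_genome(1000)
  tr <- signal_track(list(sim1 = c(5, 3, rep(0, 8))), bin_size = 100,
                     genome = g, total_reads = 1e6)
  cpm <- cpm_normalize(tr)
  expect_equal(cpm$values[[1]][1:2], c(5, 3))
  tr2 <- signal_track(list(sim1 = c(3, rep(0, 9))), bin_size = 100,
                      genome = g, total_reads = 2e6)
  expect_equal(cpm_normalize(tr2)$values[[1]][1], 1.5)

  reads <- test_reads(withr::with_seed(1, sample(900, 400, TRUE)), g)
  full <- cpm_normalize(coverage_track(reads, 100))
  expect_equal(sum(full$values[[1]]), 1e6)

  expect_error(cpm_normalize(full), "already")
  zero <- signal_track(list(sim1 = rep(0, 10)), 100, g, total_reads = 0)
  expect_error(cpm_normalize(zero), "zero")
})

test_that("bedGraph write/read round-trips tracks", {
  g <- test_genome(1e5)
  reads <- simulate_reads(test_sites(5e4, g), kernel_resection_early(),
                          total_reads = 2000, seed = 1)
  tr <- cpm_normalize(coverage_track(reads, 100))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(back$bin_size, tr$bin_size)
  expect_equal(back$normalized, tr$normalized)
  expect_equal(back$total_reads, tr$total_reads)
  expect_equal(back$values[[1]], tr$values[[1]], tolerance = 1e-5)

  # empty track -> header-only file that reads back as all zeros
  empty <- signal_track(list(sim1 = rep(0, 1000)), 100, g, total_reads = 10)
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(empty, f2)
  expect_false(any(grepl("^sim1", readLines(f2))))
  expect_equal(read_bedgraph(f2)$values[[1]], rep(0, 1000))
})

test_that("hand-written bedGraph reads into the expected bins", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("sim1\t0\t100\t2.5",
               "sim1\t300\t400\t1",
               "sim1\t500\t700\t4"), f)
  tr <- read_bedgraph(f, bin_size = 100, genome = test_genome(1000))
  v <- tr$values[[1]]
  expect_equal(which(v != 0), c(1, 4, 6, 7))
  expect_equal(v[c(1, 4, 6, 7)], c(2.5, 1, 4, 4))

  writeLines(c("sim1\t0\t100\t1", "sim1\t50\t150\t2"), f)
  expect_error(read_bedgraph(f, bin_size = 100, genome = test_genome(1000)),
               "overlapping")
  writeLines("sim1\t30\t130\t1", f)
  expect_error(read_bedgraph(f, bin_size = 100, genome = test_genome(1000)),
               "bin grid")
})
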