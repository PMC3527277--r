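# Helper: a GRanges of n disjoint "peaks" with ranking metadata.
make_peaks <- function(n, chrom = "chr1", start0 = 1000, gap = 2000,
                       p_values = 10^-(rev(seq_len(n)) + 4)) {  # row 1 = best rank
  pk <- GRanges(chrom, IRanges(start0 + (seq_len(n) - 1) * gap, width = 400))
  mcols(pk) <- DataFrame(summit = start(pk) + 200L,
                         height = rev(seq_len(n)) + 10L,
                         n_reads = rev(seq_len(n)) * 2L + 20L,
                         fold = rev(seq_len(n)) / 2 + 1,
                         p_value = p_values)
  pk
}

test_that("classify_sites partitions control peaks exactly", {
  ctl <- make_peaks(20)
  # identical sets: everything persistent
  res <- classify_sites(ctl, ctl)
  expect_length(res$persistent, 20L)
  expect_length(res$control_only, 0L)
  expect_length(res$mitotic_only, 0L)
  # disjoint sets
  mit <- shift(ctl, 1000)  # offset interleaves into the gaps
  mit <- mit[!overlapsAny(mit, ctl)]
  res2 <- classify_sites(ctl, mit)
  expect_length(res2$persistent, 0L)
  expect_length(res2$control_only, 20L)
  expect_length(res2$mitotic_only, length(mit))
  # partition invariant on random subsets
  set.seed(51)
  for (rep in 1:10) {
    keep <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    res3 <- classify_sites(ctl, ctl[keep])
    expect_equal(length(res3$persistent) + length(res3$control_only), 20L)
    expect_length(res3$mitotic_only, 0L)
    expect_equal(granges(res3$persistent), granges(ctl[keep]))
  }
})

test_that("classify_sites rejects overlapping peaks within one condition", {
  bad <- GRanges("chr1", IRanges(c(100, 300), width = 400))
  mcols(bad) <- DataFrame(p_value = c(1e-9, 1e-8))
  ok <- make_peaks(3)
  expect_error(classify_sites(bad, ok), "overlap each other")
  expect_error(classify_sites(ok, bad), "overlap each other")
})

test_that("a mitotic peak spanning two control peaks pairs with the larger overlap", {
  ctl <- GRanges("chr1", IRanges(c(1000, 1600), width = 400))
  mcols(ctl) <- DataFrame(p_value = c(1e-6, 1e-9), n_reads = c(5L, 50L))
  mit <- GRanges("chr1", IRanges(1300, width = 500))  # 100 bp vs 200 bp overlap
  mcols(mit) <- DataFrame(p_value = 1e-7, n_reads = 20L)
  res <- classify_sites(ctl, mit)
  expect_equal(res$pairing$control_idx, 2L)
  expect_length(res$persistent, 2L)  # both control peaks touch the mitotic one
})

test_that("decile retention reproduces hand-computable configurations", {
  ctl <- make_peaks(100)
  # mitotic = exactly the top decile by every metric (rows 1:10 are best)
  top <- ctl[1:10]
  for (m in c("p_value", "n_reads", "height", "fold")) {
    expect_equal(decile_retention(ctl, m, top),
                 c(100, rep(0, 9)))
  }
  # mitotic = control: uniform 10% per decile (n divisible by 10)
  expect_equal(decile_retention(ctl, "p_value", ctl), rep(10, 10))
  # remainder spread over leading deciles: 103 peaks -> sizes 11,11,11,10...
  ctl2 <- make_peaks(103)
  expect_equal(decile_retention(ctl2, "p_value", ctl2[1:11]),
               c(100, rep(0, 9)))
  expect_error(decile_retention(make_peaks(5), "p_value", make_peaks(5)),
               ">= 10")
})

test_that("decile retention sums to 100 when all mitotic peaks are paired", {
  set.seed(52)
  ctl <- make_peaks(97)
  mit <- ctl[sample(97, 40)]
  out <- decile_retention(ctl, "n_reads", mit)
  expect_true(all(out >= 0 & out <= 100))
  expect_equal(sum(out), 100)
})

test_that("occupancy-biased retention enriches the top decile end to end", {
  cfg <- sim_config(n_sites = 500, genome = c(chrA = 2e6, chrB = 2e6),
                    depth = 500 * 50, retained_fraction = 0.1,
                    occupancy_scale = 0.3, retention_bias = 2,
                    min_gap = 500, no_retention_chrom = NULL, seed = 53)
  sim <- simulate_experiment(cfg)
  pc <- call_condition_peaks(sim$control, sim$input, cfg$genome)
  pm <- call_condition_peaks(sim$mitotic, sim$input, cfg$genome)
  for (m in c("p_value", "n_reads")) {
    dec <- decile_retention(pc, m, pm)
    expect_gt(dec[1], dec[10])
    expect_gt(dec[1], 15)   # clearly enriched over the uniform 10%
  }
})

test_that("reads-in-peaks correlation behaves on constructed counts", {
  genome <- c(chr1 = 1e6)
  peaks <- GRanges("chr1", IRanges(c(1, 3, 5) * 1e5, width = 1000),
                   seqlengths = genome)
  mk <- function(counts) {
    pos <- unlist(mapply(function(s, n) s + seq_len(n) * 10, start(peaks),
                         counts))
    read_set(GRanges("chr1", IRanges(pos, width = 1), strand = "+",
                     seqlengths = genome))
  }
  a <- mk(c(10, 20, 30))
  expect_equal(reads_in_peaks_correlation(peaks, a, a), 1.0)
  b <- mk(c(30, 20, 10))
  expect_equal(reads_in_peaks_correlation(peaks, a, b), -1.0)
  # symmetry
  set.seed(54)
  c1 <- mk(sample(5:50, 3)); c2 <- mk(sample(5:50, 3))
  expect_equal(reads_in_peaks_correlation(peaks, c1, c2),
               reads_in_peaks_correlation(peaks, c2, c1))
  # degenerate: constant counts
  flat <- mk(c(10, 10, 10))
  expect_error(reads_in_peaks_correlation(peaks, flat, a), "variance")
  expect_error(reads_in_peaks_correlation(peaks[1], a, a), ">= 2")
})

test_that("correlation recovers a known bivariate Poisson correlation", {
  set.seed(55)
  n <- 500
  genome <- c(chr1 = as.integer(n * 3000 + 10000))
  peaks <- GRanges("chr1", IRanges(seq_len(n) * 3000, width = 800),
                   seqlengths = genome)
  mu <- 40
  common <- rpois(n, 0.8 * mu)
  ka <- common + rpois(n, 0.2 * mu)   # corr(ka, kb) = 0.8 by construction
  kb <- common + rpois(n, 0.2 * mu)
  mk <- function(counts) {
    pos <- unlist(mapply(function(s, k) if (k > 0) s + seq_len(k) else integer(0),
                         start(peaks), counts))
    read_set(GRanges("chr1", IRanges(pos, width = 1), strand = "+",
                     seqlengths = genome))
  }
  r <- reads_in_peaks_correlation(peaks, mk(ka), mk(kb))
  expect_lt(abs(r - 0.8), 0.08)
})

test_that("retention results are written as three BEDs plus a summary", {
  ctl <- make_peaks(30)
  res <- classify_sites(ctl, ctl[1:12])
  dir <- withr::local_tempdir()
  paths <- write_retention(res, dir)
  expect_true(all(file.exists(paths)))
  expect_length(read_bed(paths[1]), 12L)
  expect_length(read_bed(paths[2]), 18L)
  summ <- read.delim(paths[4])
  expect_equal(summ$n, c(12L, 18L, 0L))
})
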