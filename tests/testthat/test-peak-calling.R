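genome1 <- c(chr1 = 1e6)

test_that("fragment extension covers the expected span per strand", {
  rs <- read_set(GRanges("chr1", IRanges(c(100, 500), width = 1),
                         strand = c("+", "-"), seqlengths = genome1))
  tr <- extend_and_pileup(rs, 36)
  cov <- as.numeric(tr$cov[["chr1"]])
  expect_equal(which(cov == 1), c(100:135, 465:500))  # [100,136) and (464,500]
  # two stacked + reads
  rs2 <- read_set(GRanges("chr1", IRanges(c(100, 110), width = 1),
                          strand = "+", seqlengths = genome1))
  cov2 <- as.numeric(extend_and_pileup(rs2, 36)$cov[["chr1"]])
  expect_equal(which(cov2 == 2), 110:135)
  expect_equal(which(cov2 >= 1), 100:145)
})

test_that("pileup conserves read mass up to edge clipping", {
  set.seed(41)
  for (rep in 1:5) {
    rs <- uniform_reads(2000, genome1)
    tr <- extend_and_pileup(rs, 36)
    total_bp <- sum(as.numeric(sum(tr$cov)))
    clipped <- sum(36 - width(tr$frags))
    expect_equal(total_bp, 2000 * 36 - clipped)
  }
})

test_that("validation errors for bad pileup and calling parameters", {
  rs <- uniform_reads(10, genome1)
  expect_error(extend_and_pileup(rs, 0), "fragment_size")
  tr <- extend_and_pileup(rs, 36)
  expect_error(call_peaks(tr, p_cutoff = 0), "p_cutoff")
  expect_error(call_peaks(tr, bandwidth = 2e6), "bandwidth")
  empty <- read_set(GRanges(seqlengths = genome1))
  expect_length(call_peaks(extend_and_pileup(empty, 36, genome1)), 0L)
})

test_that("uniform background yields no peaks at the 1e-5 cutoff", {
  # desk-scale track: the smallest significant window count (5 reads at
  # lambda 0.235) has probability ~5e-6, far below one expected false
  # window across the ~1000 windows scanned
  set.seed(42)
  small <- c(chr1 = 1e5)
  zero_runs <- 0L
  for (i in 1:20) {
    rs <- uniform_reads(100, small)
    pk <- call_peaks(extend_and_pileup(rs, 36))
    zero_runs <- zero_runs + (length(pk) == 0L)
  }
  expect_gte(zero_runs, 19L)
})

test_that("a planted 60-read site is always called as exactly one peak", {
  set.seed(43)
  for (i in 1:10) {
    rs <- planted_reads(60, site_start = 5e5)
    pk <- call_peaks(extend_and_pileup(rs, 36))
    site <- GRanges("chr1", IRanges(5e5, width = 200))
    expect_equal(sum(overlapsAny(pk, site)), 1L)
    expect_lt(mcols(pk)$p_value[overlapsAny(pk, site)], 1e-5)
  }
})

test_that("peak p-values match the direct Poisson summation oracle", {
  set.seed(44)
  for (i in 1:5) {
    rs <- planted_reads(sample(40:100, 1), site_start = sample(2e5:8e5, 1))
    tr <- extend_and_pileup(rs, 36)
    pk <- call_peaks(tr)
    rate <- length(rs) / sum(genome1)
    lam <- rate * (width(pk) + 36 - 1)
    oracle <- pois_tail_oracle(mcols(pk)$n_reads, lam)
    expect_lt(max(abs(mcols(pk)$p_value - oracle)), 1e-12)
  }
})

test_that("Poisson tail p-value is non-increasing as reads are added", {
  p <- bookmarkR:::.pois_upper(5:50, 2.0)
  expect_true(all(diff(p) < 0))
})

test_that("called peaks are disjoint and summits sit near true site centers", {
  set.seed(45)
  cfg <- sim_config(genome = c(chrA = 1e6), n_sites = 100, depth = 100 * 50,
                    retained_fraction = 0, min_gap = 1000,
                    no_retention_chrom = NULL, seed = 45)
  sim <- simulate_experiment(cfg)
  pk <- call_peaks(extend_and_pileup(sim$control, 36, cfg$genome))
  expect_true(isDisjoint(pk))
  expect_true(all(mcols(pk)$summit >= start(pk) & mcols(pk)$summit <= end(pk)))
  hits <- findOverlaps(sim$sites, pk)
  centers <- floor((start(sim$sites) + end(sim$sites)) / 2)[queryHits(hits)]
  summits <- mcols(pk)$summit[subjectHits(hits)]
  expect_gte(mean(abs(summits - centers) <= 50), 0.95)
})

test_that("empirical FDR follows the sample-swap counting rule", {
  pk <- GRanges("chr1", IRanges(c(100, 400, 800, 1500) * 100, width = 300))
  mcols(pk) <- DataFrame(summit = start(pk) + 50, height = c(40, 30, 20, 10),
                         n_reads = c(50, 40, 30, 20), fold = c(8, 6, 4, 2),
                         p_value = c(1e-20, 1e-10, 1e-7, 1e-6))
  # empty swap: fdr 0 everywhere, all retained at 5%
  none <- pk[0]
  got <- empirical_fdr(pk, none, threshold = 0.05)
  expect_length(got, 4L)
  expect_equal(mcols(got)$fdr, rep(0, 4))
  # swap identical to treatment: fdr 1 everywhere
  got2 <- empirical_fdr(pk, pk)
  expect_equal(mcols(got2)$fdr, rep(1, 4))
  # partial swap overlap: counting rule by hand
  swap <- pk[3:4]
  got3 <- empirical_fdr(pk, swap)
  # ordered p: 1e-20 (0/1), 1e-10 (0/2), 1e-7 (1/3), 1e-6 (2/4)
  expect_equal(mcols(got3)$fdr, c(0, 0, 1 / 3, 1 / 2))
})

test_that("empirical FDR is monotone along the p-value ranking", {
  set.seed(46)
  for (rep in 1:10) {
    n <- 50
    pk <- GRanges("chr1", IRanges(seq_len(n) * 2000, width = 500))
    mcols(pk) <- DataFrame(summit = seq_len(n) * 2000 + 100,
                           height = sample(10:100, n, TRUE),
                           n_reads = sample(10:200, n, TRUE),
                           fold = runif(n, 1, 20),
                           p_value = 10^runif(n, -30, -5))
    swap <- GRanges("chr2", IRanges(seq_len(20) * 2000, width = 500))
    mcols(swap) <- DataFrame(summit = seq_len(20) * 2000, height = 1L,
                             n_reads = 1L, fold = 1,
                             p_value = 10^runif(20, -10, -5))
    got <- empirical_fdr(pk, swap)
    ord <- order(mcols(got)$p_value)
    expect_true(all(diff(mcols(got)$fdr[ord]) >= 0))
    expect_true(all(mcols(got)$fdr >= 0 & mcols(got)$fdr <= 1))
  }
})

test_that("FDR-filtered peaks on simulated data recover the planted sites", {
  cfg <- sim_config(genome = c(chrA = 1e6, chrB = 1e6), n_sites = 200,
                    depth = 200 * 50, retained_fraction = 0, min_gap = 800,
                    no_retention_chrom = NULL, seed = 47)
  sim <- simulate_experiment(cfg)
  pk <- call_condition_peaks(sim$control, sim$input, cfg$genome)
  expect_true(all(mcols(pk)$fdr <= 0.05))
  sens <- mean(overlapsAny(sim$sites, pk))
  spec_ok <- mean(overlapsAny(pk, sim$sites))
  expect_gte(sens, 0.9)
  expect_gte(spec_ok, 0.95)
})

test_that("without a swap sample the caller falls back to p-value filtering", {
  set.seed(48)
  rs <- planted_reads(80, 3e5)
  expect_message(pk <- call_condition_peaks(rs, NULL, genome1),
                 "FDR unavailable")
  expect_true(all(is.na(mcols(pk)$fdr)))
  expect_gte(length(pk), 1L)
})
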