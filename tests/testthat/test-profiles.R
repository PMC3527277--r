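genome1 <- c(chr1 = 1e6)

anchors_at <- function(centers, width = 200) {
  GRanges("chr1", IRanges(centers - width / 2, width = width),
          seqlengths = genome1)
}

test_that("profile of an empty read set is all zero", {
  empty <- read_set(GRanges(seqlengths = genome1), total_mapped = 1000)
  prof <- average_profile(empty, anchors_at(c(2e5, 5e5)), flank = 500)
  expect_equal(prof$values, rep(0, 20))
  expect_length(prof$offsets, 20L)
  expect_error(average_profile(empty, GRanges(), flank = 500), "non-empty")
  expect_error(average_profile(empty, anchors_at(5e5), flank = 525),
               "multiple")
})

test_that("uniform reads give a flat profile at the Poisson expectation", {
  set.seed(61)
  rs <- uniform_reads(20000, genome1)
  prof <- average_profile(rs, anchors_at(seq(1e5, 9e5, by = 1e4)),
                          flank = 1000)
  # expected mean pileup = rate * fragment; in RPM units
  expected <- (20000 / 1e6) * 36 * 1e6 / rs$total_mapped
  expect_lt(max(abs(prof$values - expected)) / expected, 0.25)
  # 81 anchors x 40 bins: the grand mean has a sampling SD near 2%
  expect_lt(abs(mean(prof$values) - expected) / expected, 0.06)
})

test_that("profiles are invariant under read duplication (RPM scaling)", {
  set.seed(62)
  rs <- planted_reads(100, 5e5)
  dup <- read_set(sort_intervals(c(rs$reads, rs$reads)),
                  total_mapped = 2 * rs$total_mapped)
  a <- average_profile(rs, anchors_at(5e5 + 100), flank = 500)
  b <- average_profile(dup, anchors_at(5e5 + 100), flank = 500)
  expect_equal(a$values, b$values)
})

test_that("profile mass is conserved for interior disjoint windows", {
  set.seed(63)
  rs <- uniform_reads(5000, genome1)
  anchors <- anchors_at(c(2e5, 5e5, 8e5))
  prof <- average_profile(rs, anchors, flank = 1000)
  mass <- sum(prof$values) * prof$bin_size * prof$n_sites *
    rs$total_mapped / 1e6
  # equals total fragment-bp inside the (disjoint, unclipped) windows
  tr <- extend_and_pileup(rs, 36)
  mids <- floor((start(anchors) + end(anchors)) / 2)
  v <- Views(tr$cov[["chr1"]], IRanges(mids - 1000, mids + 999))
  expect_equal(mass, sum(viewSums(v)))
})

test_that("in-region subsampling keeps the right reads and RPM scale", {
  set.seed(64)
  rs <- planted_reads(200, 5e5, n_bg = 2000)
  regions <- anchors_at(5e5 + 100, width = 300)
  all_in <- subsample_reads_in_regions(rs, regions, 1, seed = 1)
  expect_equal(length(all_in),
               sum(overlapsAny(rs$reads, regions, ignore.strand = TRUE)))
  expect_equal(all_in$total_mapped, rs$total_mapped)  # parent RPM scale kept
  none <- subsample_reads_in_regions(rs, regions, 0, seed = 1)
  expect_length(none, 0L)
  expect_error(subsample_reads_in_regions(rs, regions, 1.2), "fraction")
})

test_that("subsampling is binomial in count and deterministic given the seed", {
  set.seed(65)
  n_in <- 10000
  pos <- 4e5 + sample.int(2e5, n_in, replace = TRUE)
  rs <- read_set(GRanges("chr1", IRanges(pos, width = 1), strand = "+",
                         seqlengths = genome1))
  regions <- GRanges("chr1", IRanges(4e5, width = 2e5), seqlengths = genome1)
  sub1 <- subsample_reads_in_regions(rs, regions, 0.05, seed = 9)
  sub2 <- subsample_reads_in_regions(rs, regions, 0.05, seed = 9)
  expect_identical(start(sub1$reads), start(sub2$reads))
  expect_lt(abs(length(sub1) - 500), 3 * sqrt(10000 * 0.05 * 0.95))
})

test_that("self-comparison of an exact subsample gives a central ratio of 1", {
  set.seed(66)
  cfg <- sim_config(n_sites = 100, genome = c(chr1 = 1e6), depth = 5000,
                    retained_fraction = 0, min_gap = 800,
                    no_retention_chrom = NULL, seed = 66)
  sim <- simulate_experiment(cfg)
  regions <- resize(sim$sites, 400, fix = "center")
  fake_mitotic <- subsample_reads_in_regions(sim$control, regions, 0.05,
                                             seed = 3)
  cc <- contamination_check(sim$control, fake_mitotic, regions,
                            genome = cfg$genome, seed = 3)
  expect_equal(cc$central_ratio, 1.0)
})

test_that("true retention inflates the contamination-null ratio; pure contamination does not", {
  base <- list(n_sites = 400, genome = c(chrA = 2e6, chrB = 2e6),
               depth = 400 * 50, min_gap = 500, no_retention_chrom = NULL)
  cfg_ret <- do.call(sim_config, c(base, list(retained_fraction = 0.1,
                                              occupancy_scale = 0.3,
                                              contamination = 0, seed = 67)))
  sim <- simulate_experiment(cfg_ret)
  anchors <- sim$sites[mcols(sim$sites)$retained]
  cc <- contamination_check(sim$control, sim$mitotic, anchors,
                            genome = cfg_ret$genome, seed = 67)
  expect_gt(cc$central_ratio, 1.5)

  cfg_con <- do.call(sim_config, c(base, list(retained_fraction = 0,
                                              contamination = 0.05,
                                              seed = 68)))
  sim2 <- simulate_experiment(cfg_con)
  pc <- call_condition_peaks(sim2$control, sim2$input, cfg_con$genome)
  cc2 <- contamination_check(sim2$control, sim2$mitotic, pc,
                             genome = cfg_con$genome, seed = 68)
  expect_gt(cc2$central_ratio, 0.8)
  expect_lt(cc2$central_ratio, 1.25)
})

test_that("the per-peak carry-over filter separates retention from contamination", {
  cfg <- sim_config(n_sites = 400, genome = c(chrA = 2e6, chrB = 2e6),
                    depth = 400 * 50, retained_fraction = 0.1,
                    occupancy_scale = 0.3, contamination = 0.05,
                    retention_bias = 2, min_gap = 500,
                    no_retention_chrom = NULL, seed = 69)
  sim <- simulate_experiment(cfg)
  pm <- call_condition_peaks(sim$mitotic, sim$input, cfg$genome)
  kept <- filter_contamination_peaks(pm, sim$control, sim$mitotic)
  truth <- sim$sites[mcols(sim$sites)$retained]
  # kept peaks are predominantly true retained sites
  expect_gte(mean(overlapsAny(kept, truth)), 0.9)
  # and most true retained peaks survive the filter
  called_true <- pm[overlapsAny(pm, truth)]
  expect_gte(length(kept[overlapsAny(kept, truth)]) /
               max(1, length(called_true)), 0.9)
})
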