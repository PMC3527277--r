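# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force all-pairs interval overlap, direct
# Poisson tail summation, and exhaustive cross-entropy minimisation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# All-against-all interval overlap oracle on plain coordinate vectors.
# Returns the pair matrix (query index, subject index) for intersection
# length >= min_bp, using 1-based closed coordinates.
brute_force_overlaps <- function(s1, e1, s2, e2, min_bp = 1L) {
  pairs <- NULL
  for (i in seq_along(s1)) {
    inter <- pmin(e1[i], e2) - pmax(s1[i], s2) + 1L
    j <- which(inter >= min_bp)
    if (length(j)) pairs <- rbind(pairs, cbind(i, j))
  }
  if (is.null(pairs)) pairs <- cbind(i = integer(0), j = integer(0))
  unname(pairs)
}

# Direct upper-tail Poisson summation P(X >= k) by adding density terms
# until they vanish (independent of ppois).
pois_tail_oracle <- function(k, lambda) {
  mapply(function(ki, li) {
    i <- ki
    total <- 0
    repeat {
      term <- dpois(i, li)
      total <- total + term
      i <- i + 1
      if (term < .Machine$double.xmin || (i > ki + 30 && term < 1e-18 * max(total, 1e-300))) break
    }
    total
  }, k, lambda)
}

# Exhaustive minimiser of the Li cross-entropy objective over all
# candidate thresholds (the slow reference li_threshold is checked against).
li_threshold_oracle <- function(x) {
  x <- as.numeric(x)
  cand <- sort(unique(x))
  cand <- cand[-length(cand)]        # threshold below the max keeps 2 classes
  eps <- 1e-9
  obj <- vapply(cand, function(t) {
    b <- x[x <= t]; f <- x[x > t]
    -(sum(b) * log(mean(b) + eps) + sum(f) * log(mean(f) + eps))
  }, 0)
  cand[which.min(obj)]
}

# Random bimodal 32x32 test image with well-separated modes.
random_bimodal_image <- function() {
  n1 <- sample(300:700, 1); n2 <- 1024 - n1
  lo <- runif(1, 5, 60); hi <- runif(1, 120, 400)
  x <- c(rnorm(n1, lo, lo / 5), rnorm(n2, hi, hi / 8))
  matrix(pmax(round(x), 0), 32, 32)
}

# Random interval set on a toy genome, as raw 0-based BED-like coordinates.
random_interval_set <- function(n, genome_len = 1e6, max_width = 5000) {
  start0 <- sort(sample.int(genome_len - max_width, n, replace = TRUE)) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  list(start0 = start0, end0 = start0 + width)
}

# GRanges from 0-based half-open coordinates on one toy chromosome.
gr_from_bed0 <- function(start0, end0, chrom = "chr1", genome_len = 1e6) {
  GRanges(chrom, IRanges(start0 + 1L, end0),
          seqlengths = setNames(genome_len, chrom))
}

# A ReadSet of uniform background reads on one chromosome.
uniform_reads <- function(n, genome = c(chr1 = 1e6)) {
  chr <- sample(names(genome), n, replace = TRUE, prob = genome / sum(genome))
  pos <- floor(runif(n) * genome[chr]) + 1L
  read_set(GRanges(chr, IRanges(pos, width = 1L),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   seqlengths = genome))
}

# A ReadSet with a site of `n_site` reads planted on a uniform background.
planted_reads <- function(n_site, site_start, site_width = 200,
                          n_bg = 1000, genome = c(chr1 = 1e6),
                          fragment_size = 36) {
  bg <- uniform_reads(n_bg, genome)$reads
  fs <- site_start + floor(runif(n_site) * (site_width - fragment_size + 1))
  str <- sample(c("+", "-"), n_site, replace = TRUE)
  pos <- ifelse(str == "+", fs, fs + fragment_size - 1)
  sig <- GRanges(names(genome)[1], IRanges(pos, width = 1L), strand = str,
                 seqlengths = genome)
  read_set(sort_intervals(c(bg, sig)))
}
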