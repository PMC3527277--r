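# RPM-normalised average read-density profiles around anchor sets, and the
# subsampled-control contamination null: if mitotic peaks were nothing but
# <= 5% interphase carry-over, the mitotic average profile could not exceed
# the profile built from 5% of the control reads in peak regions kept on
# the control's RPM scale.

#' Average fragment-density profile around anchor midpoints
#'
#' For each anchor midpoint, fragment pileup is accumulated in consecutive
#' `bin_size`-bp bins across `[mid - flank, mid + flank)`, averaged over
#' anchors, and scaled to reads-per-million by `1e6 / total_mapped`. Each
#' bin value is the mean fragment pileup in the bin, i.e.
#' (fragment-bp in bin) / bin_size, averaged over anchors. Windows
#' reaching past a chromosome end are clipped and the affected anchors are
#' counted in `n_clipped`.
#'
#' @param rs A [read_set()].
#' @param anchors Non-empty `GRanges`; midpoints are the profile anchors.
#' @param flank Half-window in bp; must be a multiple of `bin_size`.
#' @param bin_size Bin width in bp (default 50).
#' @param fragment_size Fragment extension in bp.
#' @param genome Named chromosome lengths; defaults to seqlengths of the
#'   reads.
#' @return A list of class `average_profile` with `offsets` (bin-centre
#'   offsets relative to the anchor, bp), `values` (RPM per bin),
#'   `bin_size`, `flank`, `n_sites`, `n_clipped`, `total_mapped`.
#' @export
average_profile <- function(rs, anchors, flank = 1000, bin_size = 50,
                            fragment_size = 36, genome = NULL) {
  if (length(anchors) == 0) stop("anchors must be non-empty")
  if (flank %% bin_size != 0) stop("flank must be a multiple of bin_size")
  track <- extend_and_pileup(rs, fragment_size, genome)
  nbin <- as.integer(2 * flank / bin_size)
  mids <- floor((start(anchors) + end(anchors)) / 2)
  win_start <- mids - flank            # 1-based start of first bin
  chr_all <- as.character(seqnames(anchors))
  total <- numeric(nbin)
  clipped <- 0L
  for (chr in unique(chr_all)) {
    idx <- which(chr_all == chr)
    L <- track$genome[[chr]]
    covchr <- track$cov[[chr]]
    bin_start <- rep(win_start[idx], each = nbin) +
      rep((seq_len(nbin) - 1L) * bin_size, times = length(idx))
    bin_end <- bin_start + bin_size - 1L
    clipped <- clipped + sum(win_start[idx] < 1 | (win_start[idx] + 2 * flank - 1) > L)
    s <- pmax(bin_start, 1L); e <- pmin(bin_end, L)
    ok <- s <= e
    sums <- numeric(length(bin_start))
    if (any(ok)) {
      v <- Views(covchr, IRanges(s[ok], e[ok]))
      sums[ok] <- viewSums(v)
    }
    total <- total + rowSums(matrix(sums, nrow = nbin))
  }
  values <- total / (length(anchors) * bin_size) * 1e6 / rs$total_mapped
  offsets <- -flank + (seq_len(nbin) - 0.5) * bin_size
  structure(list(offsets = offsets, values = values, bin_size = bin_size,
                 flank = flank, n_sites = length(anchors),
                 n_clipped = clipped, total_mapped = rs$total_mapped),
            class = "average_profile")
}

#' @export
print.average_profile <- function(x, ...) {
  cat("average_profile:", length(x$values), "bins of", x$bin_size,
      "bp over", x$n_sites, "anchors; peak value",
      signif(max(x$values), 4), "RPM\n")
  invisible(x)
}

#' Write an average profile as TSV
#'
#' @param profile An `average_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(offset = profile$offsets,
                         rpm = profile$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binomially subsample reads falling inside regions
#'
#' Keeps each read whose 5' position lies inside `regions` independently
#' with probability `fraction`; reads outside the regions are dropped. The
#' output keeps the *original* `total_mapped`, so profiles built from it
#' stay on the parent sample's RPM scale — this models a low-level
#' contamination of a sample sequenced at the original depth, and
#' renormalising by the subsampled count would cancel the very effect the
#' contamination null tests.
#'
#' @param rs A [read_set()].
#' @param regions `GRanges` of regions to restrict to.
#' @param fraction Keep probability in `[0, 1]`.
#' @param seed Integer seed (reproducible thinning).
#' @return A [read_set()] with the original `total_mapped`.
#' @export
subsample_reads_in_regions <- function(rs, regions, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  inside <- overlapsAny(rs$reads, regions, ignore.strand = TRUE)
  reads <- rs$reads[inside]
  set.seed(seed)
  keep <- runif(length(reads)) < fraction
  read_set(reads[keep], total_mapped = rs$total_mapped)
}

#' Contamination null: mitotic profile versus subsampled-control profile
#'
#' Builds the average profile of the mitotic reads and of a
#' `fraction`-subsample of the control reads in peak regions (kept on the
#' control RPM scale), both anchored on `peak_regions`. The headline
#' statistic is the ratio of central enrichment — the mean RPM over bins
#' within `central_bp` of the anchor, minus each profile's own flanking
#' baseline (mean of the outermost bins) — of mitotic over subsampled
#' control. Baseline subtraction matters because the mitotic sample is
#' sequenced at full depth and so carries a genome-wide background floor
#' that the in-region subsample by construction lacks. A ratio near 1 is
#' what pure interphase contamination would produce; genuine retention
#' drives it well above 1.
#'
#' @param control,mitotic [read_set()]s.
#' @param peak_regions Anchor `GRanges` (e.g. mitotic peak intervals).
#' @param fraction Contamination fraction modelled (default 0.05).
#' @param flank,bin_size,fragment_size,genome See [average_profile()].
#' @param central_bp Half-width of the central window (default 200 bp).
#' @param baseline_frac Fraction of bins at each profile edge used as the
#'   baseline (default 0.15).
#' @param seed Seed for the subsampling.
#' @return A list of class `contamination_check` with
#'   `profile_mitotic`, `profile_subsampled`, `ratio_per_bin`,
#'   `difference_per_bin`, `central_enrichment_mitotic`,
#'   `central_enrichment_subsampled` and `central_ratio`.
#' @export
contamination_check <- function(control, mitotic, peak_regions,
                                fraction = 0.05, flank = 1000,
                                bin_size = 50, fragment_size = 36,
                                genome = NULL, central_bp = 200,
                                baseline_frac = 0.15, seed = 1L) {
  sub <- subsample_reads_in_regions(control, peak_regions, fraction, seed)
  prof_m <- average_profile(mitotic, peak_regions, flank, bin_size,
                            fragment_size, genome)
  prof_s <- average_profile(sub, peak_regions, flank, bin_size,
                            fragment_size, genome)
  central <- abs(prof_m$offsets) <= central_bp
  n_edge <- max(1L, floor(baseline_frac * length(prof_m$values) / 2))
  edge <- c(seq_len(n_edge), length(prof_m$values) - seq_len(n_edge) + 1L)
  enr <- function(p) mean(p$values[central]) - mean(p$values[edge])
  e_m <- enr(prof_m); e_s <- enr(prof_s)
  structure(list(profile_mitotic = prof_m, profile_subsampled = prof_s,
                 ratio_per_bin = prof_m$values / prof_s$values,
                 difference_per_bin = prof_m$values - prof_s$values,
                 central_enrichment_mitotic = e_m,
                 central_enrichment_subsampled = e_s,
                 central_ratio = e_m / e_s),
            class = "contamination_check")
}

#' Per-peak interphase carry-over test
#'
#' For each mitotic peak, asks whether its mitotic read count could be
#' explained by carry-over of up to `fraction` of the control sample's
#' signal at that locus: the count is compared to a Poisson with mean
#' `fraction x (control fragments in the peak) x (mitotic/control depth
#' ratio)` plus the mitotic sample's genome-wide background expectation
#' in the peak, and the peak is kept only when the Benjamini-Hochberg
#' adjusted upper-tail probability across all tested peaks falls below
#' `alpha`. This is the per-peak analogue of
#' [contamination_check()]: a peak surviving it is too strong to be
#' explained by sorting impurity alone.
#'
#' @param mitotic_peaks Peak `GRanges`.
#' @param control,mitotic [read_set()]s for the two conditions.
#' @param fraction Maximum contamination fraction modelled (default
#'   0.05).
#' @param alpha Significance level of the carry-over rejection (default
#'   0.01).
#' @param fragment_size Fragment extension in bp.
#' @return The subset of `mitotic_peaks` inconsistent with pure
#'   carry-over, with a `contamination_p` metadata column added.
#' @export
filter_contamination_peaks <- function(mitotic_peaks, control, mitotic,
                                       fraction = 0.05, alpha = 0.01,
                                       fragment_size = 36) {
  if (length(mitotic_peaks) == 0) return(mitotic_peaks)
  cnt <- function(rs) {
    frags <- .extend_trim(rs$reads, fragment_size)
    countOverlaps(mitotic_peaks, frags, ignore.strand = TRUE)
  }
  k_c <- cnt(control); k_m <- cnt(mitotic)
  genome_len <- sum(seqlengths(mitotic$reads), na.rm = TRUE)
  bg_rate <- if (genome_len > 0) length(mitotic) / genome_len else 0
  lambda <- fraction * k_c * (mitotic$total_mapped / control$total_mapped) +
    bg_rate * (width(mitotic_peaks) + fragment_size - 1)
  p <- ppois(k_m - 1, lambda, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  mcols(mitotic_peaks)$contamination_p <- p
  mitotic_peaks[q < alpha]
}

#' @export
print.contamination_check <- function(x, ...) {
  cat("contamination_check: central-bin mitotic / subsampled-control ratio =",
      signif(x$central_ratio, 4), "\n")
  invisible(x)
}
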