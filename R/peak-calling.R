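# A deliberately minimal MACS-1.x-style peak caller: fixed fragment
# extension (no shift-model estimation), sliding-window Poisson scan
# against a local background rate, merge of significant windows, and
# sample-swap empirical FDR. Every free parameter of the procedure
# (fragment size, effective genome size, bandwidth, p-value cutoff, FDR
# threshold) is exposed.

#' Extend reads and compute the fragment pileup
#'
#' Each read contributes 1 to coverage over its inferred fragment:
#' `[pos, pos + fragment_size)` for `+` reads and `(pos - fragment_size,
#' pos]` for `-` reads, clipped at chromosome edges. The pileup conserves
#' mass: total coverage-bp equals reads x fragment_size minus clipping.
#'
#' @param rs A [read_set()].
#' @param fragment_size Fragment length in bp (>= 1).
#' @param genome Named integer vector of chromosome lengths; defaults to
#'   the seqlengths of the reads.
#' @return A list of class `coverage_track` with `cov` (`RleList` pileup),
#'   `frags` (extended fragments as `GRanges`), `fragment_size`,
#'   `source_reads` (stored reads), `total_mapped`, and `genome`.
#' @export
extend_and_pileup <- function(rs, fragment_size = 36, genome = NULL) {
  stopifnot(inherits(rs, "ReadSet"))
  if (fragment_size < 1) stop("fragment_size must be >= 1")
  if (is.null(genome)) {
    genome <- seqlengths(rs$reads)
    if (any(is.na(genome)) || length(genome) == 0) {
      stop("no genome map: supply `genome` or reads with seqlengths")
    }
  }
  gr <- rs$reads
  seqlevels(gr) <- names(genome)
  seqlengths(gr) <- genome
  frags <- .extend_trim(gr, fragment_size)
  cov <- coverage(frags, width = as.list(genome))
  structure(list(cov = cov, frags = frags, fragment_size = fragment_size,
                 source_reads = length(gr), total_mapped = rs$total_mapped,
                 genome = genome),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$source_reads, "reads, fragment",
      x$fragment_size, "bp,", length(x$genome), "chromosome(s)\n")
  invisible(x)
}

# Upper-tail Poisson probability P(X >= k).
.pois_upper <- function(k, lambda) {
  ppois(k - 1, lambda, lower.tail = FALSE)
}

# Expected number of fragments overlapping a window of `w` bp when
# fragment starts occur at `rate` per bp: a fragment of length f overlaps
# the window iff its start falls in a span of w + f - 1 bp.
.window_lambda <- function(rate, w, fragment_size) {
  rate * (w + fragment_size - 1)
}

# Local per-bp fragment-start rates around regions, following the MACS
# local-lambda convention: max over the genome-wide rate and rates
# estimated from the control track in windows centred on each region.
.local_rates <- function(regions, control_frags, control_total, treat_total,
                         rate_bg, local_windows, genome) {
  rate <- rep(rate_bg, length(regions))
  if (!is.null(control_frags) && length(regions)) {
    scale <- treat_total / control_total
    mid <- floor((start(regions) + end(regions)) / 2)
    chr_len <- genome[as.character(seqnames(regions))]
    for (w in local_windows) {
      win <- GRanges(seqnames(regions),
                     IRanges(pmax(1, mid - w / 2),
                             pmin(chr_len, mid + w / 2 - 1)),
                     seqlengths = genome)
      k <- countOverlaps(win, control_frags, ignore.strand = TRUE)
      rate <- pmax(rate, scale * k / width(win))
    }
  }
  rate
}

#' Call peaks from a coverage track by Poisson window scan
#'
#' Slides windows of `bandwidth` bp (step `bandwidth / 2`) along each
#' chromosome, counts fragments overlapping each window, and computes the
#' Poisson upper-tail probability against the background expectation
#' `rate * (bandwidth + fragment_size - 1)` where `rate =
#' source_reads / effective_genome_size`. Windows with `p < p_cutoff` are
#' merged when within `bandwidth` bp of each other; each merged region
#' becomes one peak scored by its own fragment count. When a control track
#' is supplied, the background rate for each peak is the maximum of the
#' genome-wide rate and depth-scaled local rates estimated from the
#' control in 1-kb and 10-kb windows (MACS local-lambda convention).
#'
#' @param track A `coverage_track` from [extend_and_pileup()].
#' @param effective_genome_size Mappable genome size in bp; defaults to
#'   the sum of the track's chromosome lengths. (For fly data the
#'   conventional value is 1.2e8.)
#' @param bandwidth Scan window size in bp.
#' @param p_cutoff Poisson p-value cutoff for candidate windows.
#' @param control_track Optional `coverage_track` of a control/input
#'   sample used for local background estimation.
#' @param local_windows Window sizes (bp) for local lambda from the
#'   control.
#' @return A `GRanges` of disjoint peaks with metadata columns `summit`
#'   (absolute coordinate of the maximum pileup), `height` (max pileup),
#'   `n_reads` (fragments overlapping the peak), `fold` (height over the
#'   expected background pileup) and `p_value`, sorted by position. Ties
#'   in p-value rank downstream are broken by `n_reads` then coordinate.
#' @export
call_peaks <- function(track, effective_genome_size = NULL, bandwidth = 200,
                       p_cutoff = 1e-5, control_track = NULL,
                       local_windows = c(1000, 10000)) {
  stopifnot(inherits(track, "coverage_track"))
  if (is.null(effective_genome_size)) effective_genome_size <- sum(track$genome)
  if (effective_genome_size <= 0) stop("effective_genome_size must be > 0")
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("p_cutoff must be in (0, 1)")
  if (any(track$genome < bandwidth)) {
    stop("genome smaller than bandwidth on some chromosome")
  }
  empty <- GRanges(seqlengths = track$genome)
  mcols(empty) <- DataFrame(summit = integer(), height = integer(),
                            n_reads = integer(), fold = numeric(),
                            p_value = numeric())
  if (track$source_reads == 0) return(empty)

  f <- track$fragment_size
  rate_bg <- track$source_reads / effective_genome_size
  step <- max(1L, as.integer(bandwidth / 2))
  windows <- unlist(GRangesList(lapply(names(track$genome), function(chr) {
    L <- track$genome[[chr]]
    starts <- seq.int(1L, max(1L, L - bandwidth + 1L), by = step)
    GRanges(chr, IRanges(starts, width = pmin(bandwidth, L - starts + 1L)),
            seqlengths = track$genome)
  })))
  k <- countOverlaps(windows, track$frags)
  lam <- .window_lambda(rate_bg, width(windows), f)
  sig <- .pois_upper(k, lam) < p_cutoff
  if (!any(sig)) return(empty)

  regions <- reduce(windows[sig], min.gapwidth = bandwidth + 1L)

  n_reads <- countOverlaps(regions, track$frags)
  height <- integer(length(regions)); summit <- integer(length(regions))
  for (chr in unique(as.character(seqnames(regions)))) {
    idx <- which(as.character(seqnames(regions)) == chr)
    v <- Views(track$cov[[chr]], ranges(regions[idx]))
    height[idx] <- viewMaxs(v)
    # summit = median of the maximum plateau of the pileup smoothed at
    # half the scan bandwidth; the raw per-bp argmax is dominated by
    # sampling spikes at realistic depths
    k <- 2L * (as.integer(bandwidth) %/% 4L) + 1L
    summit[idx] <- start(regions[idx]) - 1L +
      vapply(seq_along(v), function(j) {
        x <- as.numeric(v[[j]])
        if (k > 1 && length(x) > k) {
          xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
          xs[is.na(xs)] <- -Inf
        } else xs <- x
        as.integer(floor(stats::median(which(xs == max(xs)))))
      }, 0L)
  }

  ctl_frags <- if (!is.null(control_track)) control_track$frags else NULL
  ctl_total <- if (!is.null(control_track)) control_track$source_reads else NA
  rate_loc <- .local_rates(regions, ctl_frags, ctl_total,
                           track$source_reads, rate_bg, local_windows,
                           track$genome)
  lam_reg <- .window_lambda(rate_loc, width(regions), f)
  p_value <- pmax(.pois_upper(n_reads, lam_reg), .Machine$double.xmin)
  fold <- height / (rate_loc * f)
  mcols(regions) <- DataFrame(summit = summit, height = height,
                              n_reads = n_reads, fold = fold,
                              p_value = p_value)
  # the reported peak statistic must itself meet the cutoff: merging
  # significant windows into one region can otherwise dilute marginal calls
  regions[p_value < p_cutoff]
}

# Canonical peak ordering for FDR computation: ascending p-value, ties by
# descending n_reads then coordinate, so output is deterministic.
.peak_order <- function(peaks) {
  order(mcols(peaks)$p_value, -mcols(peaks)$n_reads,
        as.character(seqnames(peaks)), start(peaks))
}

#' Sample-swap empirical FDR for called peaks
#'
#' For each treatment peak with p-value p, the empirical FDR is
#' `#(swap peaks with p-value <= p) / #(treatment peaks with p-value <=
#' p)`, clipped to `[0, 1]` and made monotone non-decreasing along the
#' p-value ranking (step-up smoothing). Swap peaks are obtained by calling
#' peaks with treatment and control exchanged, with identical parameters.
#'
#' @param treatment_peaks,swap_peaks Peak `GRanges` from [call_peaks()].
#' @param threshold Optional FDR threshold; when given, only peaks with
#'   `fdr <= threshold` are returned.
#' @return `treatment_peaks` with an `fdr` metadata column (filtered when
#'   `threshold` is non-NULL), in position order.
#' @export
empirical_fdr <- function(treatment_peaks, swap_peaks, threshold = NULL) {
  if (length(treatment_peaks) == 0) return(treatment_peaks)
  ord <- .peak_order(treatment_peaks)
  p <- mcols(treatment_peaks)$p_value[ord]
  swap_p <- sort(mcols(swap_peaks)$p_value)
  n_swap_le <- findInterval(p, swap_p)           # swap peaks with p-value <= p
  n_treat_le <- findInterval(p, p)               # treatment peaks with p-value <= p
  fdr <- pmin(pmax(n_swap_le / n_treat_le, 0), 1)
  fdr <- cummax(fdr)                              # monotone along p-value rank
  out <- treatment_peaks
  mcols(out)$fdr <- NA_real_
  mcols(out)$fdr[ord] <- fdr
  if (!is.null(threshold)) out <- out[!is.na(mcols(out)$fdr) & mcols(out)$fdr <= threshold]
  sort_intervals(out)
}

#' Call and FDR-filter peaks for one condition
#'
#' Convenience wrapper: extends and piles up the treatment reads, calls
#' peaks, and, when a swap read set is supplied, computes the sample-swap
#' empirical FDR and filters at `fdr_threshold`. Without a swap sample the
#' FDR is undefined (`NA`) and filtering falls back to the p-value cutoff
#' alone, with a message.
#'
#' @param rs Treatment [read_set()].
#' @param swap_rs Optional read set (e.g. input) used both as the local-
#'   lambda control and, swapped, for empirical FDR.
#' @param genome Named chromosome lengths.
#' @param fragment_size,effective_genome_size,bandwidth,p_cutoff See
#'   [call_peaks()].
#' @param fdr_threshold Empirical FDR threshold (default 0.05).
#' @param drop_chroms Chromosomes whose peaks are removed after calling
#'   (e.g. unassembled scaffolds).
#' @return Peak `GRanges` with `fdr` column.
#' @export
call_condition_peaks <- function(rs, swap_rs = NULL, genome = NULL,
                                 fragment_size = 36,
                                 effective_genome_size = NULL,
                                 bandwidth = 200, p_cutoff = 1e-5,
                                 fdr_threshold = 0.05,
                                 drop_chroms = c("chrU", "chrUextra")) {
  track <- extend_and_pileup(rs, fragment_size, genome)
  if (!is.null(swap_rs)) {
    ctl_track <- extend_and_pileup(swap_rs, fragment_size, track$genome)
    peaks <- call_peaks(track, effective_genome_size, bandwidth, p_cutoff,
                        control_track = ctl_track)
    swap_peaks <- call_peaks(ctl_track, effective_genome_size, bandwidth,
                             p_cutoff, control_track = track)
    peaks <- empirical_fdr(peaks, swap_peaks, threshold = fdr_threshold)
  } else {
    message("no swap/control sample: empirical FDR unavailable, ",
            "filtering by p-value cutoff only")
    peaks <- call_peaks(track, effective_genome_size, bandwidth, p_cutoff)
    mcols(peaks)$fdr <- NA_real_
  }
  filter_chromosomes(peaks, drop_chroms)
}

#' Write peaks as a TSV table (plus optional plain BED)
#'
#' Columns: chrom, start (0-based), end, name, summit, height, n_reads,
#' fold, minus_log10_p, fdr.
#'
#' @param peaks Peak `GRanges`.
#' @param path Output TSV path.
#' @param bed_path Optional additional plain BED6 output.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, bed_path = NULL) {
  m <- mcols(peaks)
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = sprintf("peak_%05d", seq_along(peaks)),
                   summit = m$summit, height = m$height,
                   n_reads = m$n_reads, fold = round(m$fold, 4),
                   minus_log10_p = round(-log10(m$p_value), 4),
                   fdr = if (!is.null(m$fdr)) round(m$fdr, 6) else NA_real_)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- peaks
    mcols(bed) <- DataFrame(name = df$name, score = df$minus_log10_p)
    write_bed(bed, bed_path)
  }
  invisible(path)
}
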