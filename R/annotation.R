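# Annotation of peak sets against external feature sets: TSS proximity,
# chromatin-domain border / insulator overlap summaries, and
# chromosome-level and windowed distribution comparisons.

#' Read a TSS table
#'
#' Tab-separated columns `gene_id`, `chrom`, `tss` (0-based bp), `strand`,
#' with or without a header line.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those four columns.
#' @export
read_tss <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  tab <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("TSS table needs >= 3 columns (gene_id, chrom, tss)")
  if (ncol(tab) == 3) tab$strand <- "+"
  names(tab)[1:4] <- c("gene_id", "chrom", "tss", "strand")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids in TSS table")
  tab
}

#' Genes whose TSS lies within a distance of some peak
#'
#' A gene is reported when at least one peak has >= 1 bp within the closed
#' window `[tss - max_dist, tss + max_dist]`; a peak ending exactly
#' `max_dist + 1` bp away is excluded. The distance reported per gene is
#' the nearest peak's edge-to-TSS distance (0 when a peak covers the
#' TSS). Strand is ignored (the window is symmetric).
#'
#' @param peaks Peak `GRanges`.
#' @param tss TSS table from [read_tss()] (or equivalent data.frame).
#' @param max_dist Window half-width in bp (default 2000).
#' @return data.frame (`gene_id`, `distance`, `peak_idx`) with one row per
#'   bound gene.
#' @export
genes_near_peaks <- function(peaks, tss, max_dist = 2000) {
  if (is.null(tss) || nrow(tss) == 0) stop("empty TSS table")
  pts <- GRanges(tss$chrom, IRanges(tss$tss + 1L, width = 1L))
  win <- suppressWarnings(GRanges(tss$chrom,
                                  IRanges(pmax(1L, tss$tss + 1L - max_dist),
                                          tss$tss + 1L + max_dist)))
  hits <- findOverlaps(win, peaks, ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(data.frame(gene_id = character(), distance = integer(),
                      peak_idx = integer()))
  }
  g <- queryHits(hits); pk <- subjectHits(hits)
  tss_pos <- tss$tss[g] + 1L
  d <- pmax(0L, pmax(start(peaks)[pk] - tss_pos, tss_pos - end(peaks)[pk]))
  ord <- order(g, d, pk)
  first <- !duplicated(g[ord])
  sel <- ord[first]
  data.frame(gene_id = tss$gene_id[g[sel]], distance = d[sel],
             peak_idx = pk[sel])
}

#' Overlap summary of one query set against one subject set
#'
#' @param query,subject `GRanges`.
#' @param min_bp Minimum overlap in bp.
#' @return data.frame with `n_query`, `n_query_overlapping`, `n_subject`,
#'   `n_subject_overlapped` and both fractions.
#' @export
overlap_summary <- function(query, subject, min_bp = 1L) {
  fwd <- overlap_pairs(query, subject, min_bp)
  rev <- overlap_pairs(subject, query, min_bp)
  data.frame(n_query = length(query),
             n_query_overlapping = fwd$n_a_overlapping,
             n_subject = length(subject),
             n_subject_overlapped = rev$n_a_overlapping,
             frac_query = fwd$n_a_overlapping / max(1L, length(query)),
             frac_subject = rev$n_a_overlapping / max(1L, length(subject)))
}

#' Border overlap summary for control and mitotic peak sets
#'
#' For each condition, reports the fraction of peaks overlapping at least
#' one chromatin-domain border and the fraction of borders overlapped by
#' at least one peak, plus the preferential-retention ratio: (fraction of
#' mitotic peaks at borders) / (fraction of control peaks at borders). A
#' ratio above 1 means border sites are preferentially retained in
#' mitosis.
#'
#' @param control_peaks,mitotic_peaks Peak `GRanges`.
#' @param borders Border `GRanges` (non-empty).
#' @param min_bp Minimum overlap in bp.
#' @return A list with `control`, `mitotic` (overlap summaries) and
#'   `preferential_retention_ratio`.
#' @export
border_overlap_summary <- function(control_peaks, mitotic_peaks, borders,
                                   min_bp = 1L) {
  if (length(borders) == 0) stop("empty border set")
  ctl <- overlap_summary(control_peaks, borders, min_bp)
  mit <- overlap_summary(mitotic_peaks, borders, min_bp)
  ratio <- if (ctl$frac_query > 0) mit$frac_query / ctl$frac_query else NA_real_
  list(control = ctl, mitotic = mit,
       preferential_retention_ratio = ratio)
}

#' Per-chromosome distribution of peaks in two conditions
#'
#' @param peaks_control,peaks_mitotic Non-empty peak `GRanges`.
#' @return data.frame (`chrom`, `pct_control`, `pct_mitotic`, `diff`)
#'   where each percentage column sums to 100 and
#'   `diff = pct_control - pct_mitotic`.
#' @export
chromosome_distribution <- function(peaks_control, peaks_mitotic) {
  if (length(peaks_control) == 0 || length(peaks_mitotic) == 0) {
    stop("peak sets must be non-empty")
  }
  chroms <- sort(unique(c(as.character(seqnames(peaks_control)),
                          as.character(seqnames(peaks_mitotic)))))
  pct <- function(pk) {
    n <- table(factor(as.character(seqnames(pk)), levels = chroms))
    100 * as.numeric(n) / length(pk)
  }
  a <- pct(peaks_control); b <- pct(peaks_mitotic)
  data.frame(chrom = chroms, pct_control = a, pct_mitotic = b,
             diff = a - b)
}

#' Windowed difference in peak distribution between conditions
#'
#' Tiles the genome in `window`-bp windows (the last window of each
#' chromosome may be shorter), assigns each peak to the window containing
#' its midpoint, converts counts to percentages of each condition's total
#' and reports `pct_control - pct_mitotic` per window. Both percentage
#' columns sum to 100, so the differences sum to 0.
#'
#' @param peaks_control,peaks_mitotic Non-empty peak `GRanges`.
#' @param genome Named chromosome lengths.
#' @param window Window size in bp (default 5e6).
#' @return data.frame (`chrom`, `start` 0-based, `end`, `pct_control`,
#'   `pct_mitotic`, `diff`).
#' @export
windowed_site_difference <- function(peaks_control, peaks_mitotic, genome,
                                     window = 5e6) {
  if (window < 1) stop("window must be >= 1")
  if (window > max(genome)) {
    warning("window exceeds the longest chromosome; one window per chromosome")
  }
  tiles <- unlist(GRangesList(lapply(names(genome), function(chr) {
    starts <- seq.int(1L, genome[[chr]], by = window)
    GRanges(chr, IRanges(starts, pmin(starts + window - 1, genome[[chr]])))
  })))
  assign_pct <- function(pk) {
    mids <- GRanges(seqnames(pk),
                    IRanges(floor((start(pk) + end(pk)) / 2), width = 1L))
    100 * countOverlaps(tiles, mids, ignore.strand = TRUE) / length(pk)
  }
  a <- assign_pct(peaks_control); b <- assign_pct(peaks_mitotic)
  data.frame(chrom = as.character(seqnames(tiles)), start = start(tiles) - 1L,
             end = end(tiles), pct_control = a, pct_mitotic = b,
             diff = a - b)
}
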