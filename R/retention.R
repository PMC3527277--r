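# Two-condition peak-set comparison: which control sites persist in
# mitosis, how retention depends on peak rank, and how correlated the two
# binding profiles are over the union of peaks.

#' Classify control and mitotic peaks into persistent / condition-only sets
#'
#' A control peak is *persistent* when it overlaps at least one mitotic
#' peak by `min_bp`; otherwise it is *control-only*. Mitotic peaks
#' overlapping no control peak are *mitotic-only*. Each mitotic peak is
#' paired to the control peak with the largest intersection (ties to the
#' better-ranked control peak by p-value, then coordinate).
#'
#' @param control,mitotic Peak `GRanges` (disjoint within each condition).
#' @param min_bp Minimum overlap in bp (default 1).
#' @return A list of class `retention_result` with `persistent`,
#'   `control_only`, `mitotic_only` (`GRanges`) and `pairing`
#'   (data.frame of `control_idx`, `mitotic_idx`).
#' @export
classify_sites <- function(control, mitotic, min_bp = 1L) {
  for (nm in c("control", "mitotic")) {
    pk <- get(nm)
    if (length(pk) > 1 && !isDisjoint(pk, ignore.strand = TRUE)) {
      stop("validation error: ", nm, " peaks overlap each other ",
           "(upstream calling bug)")
    }
  }
  op <- overlap_pairs(control, mitotic, min_bp = min_bp)
  persistent_idx <- unique(op$pairs[, "a_idx"])
  mitotic_hit <- unique(op$pairs[, "b_idx"])
  pairing <- .assign_mitotic_partners(control, mitotic, op$pairs)
  structure(list(persistent = control[sort(persistent_idx)],
                 control_only = control[setdiff(seq_along(control), persistent_idx)],
                 mitotic_only = mitotic[setdiff(seq_along(mitotic), mitotic_hit)],
                 pairing = pairing),
            class = "retention_result")
}

# One control partner per mitotic peak: largest intersection, ties broken
# by control p-value (when present) then coordinate.
.assign_mitotic_partners <- function(control, mitotic, pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(control_idx = integer(), mitotic_idx = integer()))
  }
  inter <- width(pintersect(ranges(control)[pairs[, "a_idx"]],
                            ranges(mitotic)[pairs[, "b_idx"]]))
  p <- mcols(control)$p_value
  rank_key <- if (!is.null(p)) p[pairs[, "a_idx"]] else rep(0, nrow(pairs))
  ord <- order(pairs[, "b_idx"], -inter, rank_key, pairs[, "a_idx"])
  first <- !duplicated(pairs[ord, "b_idx"])
  sel <- ord[first]
  data.frame(control_idx = pairs[sel, "a_idx"],
             mitotic_idx = pairs[sel, "b_idx"])
}

#' @export
print.retention_result <- function(x, ...) {
  cat("retention_result:", length(x$persistent), "persistent,",
      length(x$control_only), "control-only,",
      length(x$mitotic_only), "mitotic-only peaks\n")
  invisible(x)
}

#' Percentage of mitotic peaks per decile of ranked control peaks
#'
#' Control peaks are ranked best-first by the chosen metric (ascending
#' p-value; descending reads, height or fold) and split into 10 equal
#' deciles (when the count is not divisible by 10, the leading deciles get
#' one extra peak). Each mitotic peak is assigned to its control partner's
#' decile; the output is the percentage of partnered mitotic peaks per
#' decile and sums to 100 when every mitotic peak has a partner.
#'
#' @param control,mitotic Peak `GRanges`; `control` needs the metric
#'   column and at least 10 peaks.
#' @param metric One of `"p_value"`, `"n_reads"`, `"height"`, `"fold"`.
#' @param min_bp Minimum pairing overlap in bp.
#' @return Numeric vector of 10 percentages (decile 1 = best-ranked).
#' @export
decile_retention <- function(control, metric = c("p_value", "n_reads",
                                                 "height", "fold"),
                             mitotic, min_bp = 1L) {
  metric <- match.arg(metric)
  if (length(control) < 10) stop("need >= 10 control peaks for deciles")
  vals <- mcols(control)[[metric]]
  if (is.null(vals)) stop("metric '", metric, "' missing from control peaks")
  ord <- if (metric == "p_value") {
    order(vals, -mcols(control)$n_reads, as.character(seqnames(control)),
          start(control))
  } else {
    order(-vals, as.character(seqnames(control)), start(control))
  }
  n <- length(control)
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  decile_of_rank <- rep(seq_len(10L), times = sizes)
  decile <- integer(n)
  decile[ord] <- decile_of_rank

  pairing <- classify_sites(control, mitotic, min_bp = min_bp)$pairing
  if (nrow(pairing) == 0) {
    stop("no mitotic peak has a control partner; decile retention undefined")
  }
  tab <- tabulate(decile[pairing$control_idx], nbins = 10L)
  100 * tab / nrow(pairing)
}

#' Pearson correlation of per-peak read counts between two samples
#'
#' Counts, for every interval of the peak union, the reads of each sample
#' whose extended fragment overlaps it, and returns the Pearson
#' correlation of the paired counts.
#'
#' @param peak_union `GRanges` of >= 2 intervals (typically
#'   `reduce(c(peaks_a, peaks_b))`).
#' @param reads_a,reads_b [read_set()]s.
#' @param fragment_size Fragment extension in bp (as used in calling).
#' @return Pearson r in `[-1, 1]`.
#' @export
reads_in_peaks_correlation <- function(peak_union, reads_a, reads_b,
                                       fragment_size = 36) {
  if (length(peak_union) < 2) stop("need >= 2 peaks for a correlation")
  cnt <- function(rs) {
    frags <- .extend_trim(rs$reads, fragment_size)
    countOverlaps(peak_union, frags, ignore.strand = TRUE)
  }
  a <- cnt(reads_a); b <- cnt(reads_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in per-peak counts; correlation undefined")
  }
  stats::cor(a, b)
}

#' Write a retention result as BED files plus a summary TSV
#'
#' @param res A `retention_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisible character vector of paths written.
#' @export
write_retention <- function(res, dir, prefix = "retention") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("persistent.bed", "control_only.bed",
                                   "mitotic_only.bed", "summary.tsv")))
  write_bed(res$persistent, paths[1])
  write_bed(res$control_only, paths[2])
  write_bed(res$mitotic_only, paths[3])
  n_control <- length(res$persistent) + length(res$control_only)
  summary <- data.frame(
    set = c("persistent", "control_only", "mitotic_only"),
    n = c(length(res$persistent), length(res$control_only),
          length(res$mitotic_only)),
    fraction_of_control = round(c(length(res$persistent),
                                  length(res$control_only), NA) /
                                  n_control, 4))
  write.table(summary, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
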