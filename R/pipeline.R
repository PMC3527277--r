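# End-to-end orchestration of the three analyses: two-condition ChIP-seq
# retention, fractionation quantification, and image colocalization. All
# randomness flows from the single config seed; outputs and the manifest
# are deterministic functions of (inputs, config), so repeated runs are
# byte-identical.

#' Pipeline configuration
#'
#' Defaults follow the conventional ChIP-seq analysis parameterisation
#' this package implements: 36-bp fragment extension, 200-bp scan
#' bandwidth, Poisson p-value cutoff 1e-5, 5% sample-swap FDR, 50-bp
#' profile bins, 2-kb TSS windows, 5-Mbp distribution windows, 5%
#' contamination-null subsampling, and removal of peaks on unassembled
#' chrU/chrUextra scaffolds. `effective_genome_size = NULL` means "sum of
#' the genome map"; for real fly (dm3) data the conventional mappable
#' size is 1.2e8 bp.
#'
#' @param fragment_size Fragment extension in bp.
#' @param effective_genome_size Mappable genome size in bp or `NULL`.
#' @param bandwidth Scan window in bp.
#' @param p_cutoff Poisson p-value cutoff.
#' @param fdr FDR threshold for peak retention.
#' @param bin_size Profile bin in bp.
#' @param flank Profile half-window in bp.
#' @param tss_dist TSS assignment window half-width in bp.
#' @param window Distribution window in bp.
#' @param subsample Contamination-null fraction (also the carry-over
#'   bound of the per-peak contamination filter).
#' @param contamination_alpha Significance level of the per-peak
#'   carry-over test applied to mitotic peaks (see
#'   [filter_contamination_peaks()]); `NA` disables the filter.
#' @param drop_chroms Chromosomes dropped after peak calling.
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fragment_size = 36, effective_genome_size = NULL,
                            bandwidth = 200, p_cutoff = 1e-5, fdr = 0.05,
                            bin_size = 50, flank = 1000, tss_dist = 2000,
                            window = 5e6, subsample = 0.05,
                            contamination_alpha = 0.01,
                            drop_chroms = c("chrU", "chrUextra"),
                            seed = 1L) {
  stopifnot(fragment_size >= 1, bandwidth >= 1, p_cutoff > 0, p_cutoff < 1,
            fdr >= 0, fdr <= 1, bin_size >= 1, flank %% bin_size == 0,
            tss_dist >= 0, window >= 1, subsample >= 0, subsample <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# Manifest: parameters, package version and input digests. Deliberately
# timestamp-free so identical runs are byte-identical.
.write_manifest <- function(out_dir, config, inputs, outputs) {
  manifest <- list(
    package = "bookmarkR",
    version = as.character(utils::packageVersion("bookmarkR")),
    parameters = config[setdiff(names(config), "drop_chroms")],
    drop_chroms = config$drop_chroms,
    input_digests = inputs,
    outputs = sort(basename(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full two-condition retention analysis
#'
#' Calls peaks in both conditions (with sample-swap FDR against the input
#' sample), classifies persistent / control-only / mitotic-only sites,
#' computes decile retention for all four ranking metrics, average
#' profiles, the contamination null, reads-in-peaks correlation, and —
#' when borders or a TSS table are supplied — border overlap summaries,
#' gene assignment and chromosome/window distributions. All outputs are
#' written under `out_dir` together with a machine-readable manifest.
#'
#' @param control,mitotic [read_set()]s for the two conditions.
#' @param input Optional signal-free [read_set()] used as the swap sample
#'   for FDR (without it, filtering falls back to the p-value cutoff).
#' @param genome Named chromosome lengths.
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @param borders Optional border `GRanges`.
#' @param tss Optional TSS table (see [read_tss()]).
#' @return Invisible list with the in-memory results (`peaks_control`,
#'   `peaks_mitotic`, `retention`, `deciles`, `profiles`,
#'   `contamination`, `correlation`, `border_summary`, `genes`,
#'   `chrom_distribution`, `window_difference`).
#' @export
run_retention <- function(control, mitotic, input = NULL, genome,
                          out_dir, config = pipeline_config(),
                          borders = NULL, tss = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  egs <- config$effective_genome_size
  call1 <- function(rs, swap) {
    call_condition_peaks(rs, swap_rs = swap, genome = genome,
                         fragment_size = config$fragment_size,
                         effective_genome_size = egs,
                         bandwidth = config$bandwidth,
                         p_cutoff = config$p_cutoff,
                         fdr_threshold = config$fdr,
                         drop_chroms = config$drop_chroms)
  }
  peaks_control <- call1(control, input)
  peaks_mitotic <- call1(mitotic, input)
  if (!is.na(config$contamination_alpha)) {
    peaks_mitotic <- filter_contamination_peaks(
      peaks_mitotic, control, mitotic, fraction = config$subsample,
      alpha = config$contamination_alpha,
      fragment_size = config$fragment_size)
  }

  retention <- classify_sites(peaks_control, peaks_mitotic)
  deciles <- if (length(peaks_control) >= 10 && nrow(retention$pairing) > 0) {
    sapply(c("p_value", "n_reads", "height", "fold"), function(m) {
      decile_retention(peaks_control, m, peaks_mitotic)
    })
  } else NULL

  anchors_mit <- if (length(peaks_mitotic)) peaks_mitotic else peaks_control
  profiles <- list(
    control_at_control_only = average_profile(
      control, if (length(retention$control_only)) retention$control_only else peaks_control,
      config$flank, config$bin_size, config$fragment_size, genome),
    mitotic_at_mitotic = average_profile(
      mitotic, anchors_mit, config$flank, config$bin_size,
      config$fragment_size, genome))
  contamination <- contamination_check(
    control, mitotic, anchors_mit, fraction = config$subsample,
    flank = config$flank, bin_size = config$bin_size,
    fragment_size = config$fragment_size, genome = genome,
    seed = config$seed)

  union <- reduce(c(granges(peaks_control), granges(peaks_mitotic)))
  correlation <- if (length(union) >= 2) {
    tryCatch(reads_in_peaks_correlation(union, control, mitotic,
                                        config$fragment_size),
             error = function(e) NA_real_)
  } else NA_real_

  border_summary <- if (!is.null(borders) && length(borders)) {
    border_overlap_summary(peaks_control, peaks_mitotic, borders)
  } else NULL
  genes <- if (!is.null(tss)) {
    genes_near_peaks(peaks_mitotic, tss, config$tss_dist)
  } else NULL
  chrom_dist <- if (length(peaks_control) && length(peaks_mitotic)) {
    chromosome_distribution(peaks_control, peaks_mitotic)
  } else NULL
  win_diff <- if (length(peaks_control) && length(peaks_mitotic)) {
    windowed_site_difference(peaks_control, peaks_mitotic, genome,
                             config$window)
  } else NULL

  # --- write outputs -------------------------------------------------
  paths <- character(0)
  wp <- function(fn) { p <- file.path(out_dir, fn); paths <<- c(paths, p); p }
  write_peaks(peaks_control, wp("peaks_control.tsv"), wp("peaks_control.bed"))
  write_peaks(peaks_mitotic, wp("peaks_mitotic.tsv"), wp("peaks_mitotic.bed"))
  paths <- c(paths, write_retention(retention, out_dir))
  if (!is.null(deciles)) {
    write.table(data.frame(decile = 1:10, round(deciles, 4)),
                wp("decile_retention.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_profile(profiles$control_at_control_only, wp("profile_control_only.tsv"))
  write_profile(profiles$mitotic_at_mitotic, wp("profile_mitotic.tsv"))
  write_profile(contamination$profile_subsampled, wp("profile_contamination_null.tsv"))
  write.table(data.frame(statistic = "central_ratio",
                         value = round(contamination$central_ratio, 6)),
              wp("contamination_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.na(correlation)) {
    write.table(data.frame(statistic = "reads_in_peaks_pearson_r",
                           value = round(correlation, 6)),
                wp("correlation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(border_summary)) {
    bs <- rbind(cbind(condition = "control", border_summary$control),
                cbind(condition = "mitotic", border_summary$mitotic))
    bs$preferential_retention_ratio <-
      round(border_summary$preferential_retention_ratio, 6)
    write.table(bs, wp("border_overlap.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(genes)) {
    write.table(genes, wp("genes_near_mitotic_peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(chrom_dist)) {
    write.table(chrom_dist, wp("chromosome_distribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(win_diff)) {
    write.table(win_diff, wp("window_difference.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  digests <- list(n_control_reads = length(control),
                  n_mitotic_reads = length(mitotic),
                  n_input_reads = if (!is.null(input)) length(input) else 0L,
                  genome = as.list(genome))
  .write_manifest(out_dir, config, digests, paths)

  invisible(list(peaks_control = peaks_control, peaks_mitotic = peaks_mitotic,
                 retention = retention, deciles = deciles,
                 profiles = profiles, contamination = contamination,
                 correlation = correlation, border_summary = border_summary,
                 genes = genes, chrom_distribution = chrom_dist,
                 window_difference = win_diff, out_dir = out_dir))
}

#' Run the fractionation analysis on a table file
#'
#' Reads the table, aggregates replicates, applies the mitotic-index
#' correction and writes a Table-1-style summary TSV.
#'
#' @param path Input TSV (see [read_fractionation_tsv()]).
#' @param out_path Output TSV.
#' @param values `"percent"` or `"intensity"`.
#' @return Invisible summary data.frame.
#' @export
run_fractionation <- function(path, out_path, values = "percent") {
  if (!file.exists(path)) stop("fractionation input not found: ", path)
  tab <- read_fractionation_tsv(path, values)
  summary <- summarize_fractionation(tab)
  num <- vapply(summary, is.numeric, TRUE)
  summary[num] <- round(summary[num], 4)
  write.table(summary, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Run the imaging analysis on a batch of cell image pairs
#'
#' @param pairs List of image pairs (each with `dna` and `protein`
#'   matrices).
#' @param groups Group label per pair.
#' @param out_dir Output directory; writes per-cell and per-group TSVs.
#' @return Invisible list with `cells` (per-cell data.frame) and
#'   `summary` (per-group data.frame).
#' @export
run_imaging <- function(pairs, groups, out_dir) {
  stopifnot(length(pairs) == length(groups), length(pairs) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    r <- colocalization_ratio(pairs[[i]])
    data.frame(cell = i, group = groups[i],
               pcg_dna = round(r$pcg_dna, 6),
               pcg_cyto = round(r$pcg_cyto, 6),
               ratio = round(r$ratio, 6))
  }))
  summary <- batch_summarize(cells$ratio, cells$group)
  write.table(cells, file.path(out_dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summary, file.path(out_dir, "imaging_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(cells = cells, summary = summary))
}
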