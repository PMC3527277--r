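# Subcellular-fractionation quantification. Cells are separated into a
# cytosolic supernatant (S2), its pellet (P2), a soluble nuclear fraction
# (S3) and the insoluble chromatin pellet (P3). A colchicine-arrested G2/M
# culture is only partly mitotic, so its observed P3 percentage is a
# mixture of mitotic and interphase cells; the mitotic-index correction
# inverts that mixture:
#
#   P3_mitotic = (P3_G2M - (1 - m) * P3_control) / m
#
# where m is the mitotic index of the G2/M population.

#' Normalise band intensities to percentages
#'
#' @param intensities Named non-negative numeric vector of band
#'   intensities (typically fractions S2, P2, S3, P3).
#' @return Percentages summing to 100, same names.
#' @export
normalize_fractions <- function(intensities) {
  if (any(intensities < 0)) stop("negative band intensity")
  tot <- sum(intensities)
  if (tot <= 0) stop("all-zero intensities cannot be normalised")
  100 * intensities / tot
}

#' Mitotic-index correction of the G2/M chromatin-pellet percentage
#'
#' Inverts the mixture `P3_G2M = (1 - m) * P3_control + m * P3_mitotic`
#' to isolate the chromatin-pellet percentage of the mitotic cells alone.
#' A negative result means measurement noise exceeded the mixture model;
#' it is returned as-is with a warning unless `clip = TRUE`.
#'
#' @param p3_g2m Observed G2/M percentage in the fraction.
#' @param p3_control Control percentage in the same fraction.
#' @param m Mitotic index in `(0, 1]`.
#' @param clip Clip the result into `[0, 100]` (default FALSE).
#' @return Corrected mitotic percentage.
#' @export
correct_mitotic_p3 <- function(p3_g2m, p3_control, m, clip = FALSE) {
  if (any(m <= 0) || any(m > 1)) stop("mitotic index m must be in (0, 1]")
  if (any(p3_g2m < 0 | p3_g2m > 100) || any(p3_control < 0 | p3_control > 100)) {
    stop("percentages must be in [0, 100]")
  }
  corrected <- (p3_g2m - (1 - m) * p3_control) / m
  if (any(corrected < 0)) {
    warning("negative corrected percentage: noise exceeds the mixture model")
  }
  if (clip) corrected <- pmin(pmax(corrected, 0), 100)
  corrected
}

#' Mitotic retention as percent of the control chromatin fraction
#'
#' @param corrected_gm_p3 Mitotic-corrected G2/M percentage.
#' @param control_p3 Control percentage (> 0).
#' @return `100 * corrected_gm_p3 / control_p3`.
#' @export
retention_ratio <- function(corrected_gm_p3, control_p3) {
  if (any(control_p3 <= 0)) stop("control percentage must be > 0")
  100 * corrected_gm_p3 / control_p3
}

#' Read a fractionation table
#'
#' Tab-separated with header: `protein`, `condition` (`control` or
#' `G2M`), `replicate`, `S2`, `P2`, `S3`, `P3`, `mitotic_fraction`
#' (empty/NA for control rows). Whether the four fraction columns hold
#' raw band intensities or percentages is declared by `values`; raw
#' intensities are normalised to percentages on read.
#'
#' @param path Path to the TSV.
#' @param values `"percent"` or `"intensity"`.
#' @return data.frame with percentage columns summing to ~100 per row.
#' @export
read_fractionation_tsv <- function(path, values = c("percent", "intensity")) {
  values <- match.arg(values)
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein", "condition", "replicate", "S2", "P2", "S3", "P3")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("fractionation table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"mitotic_fraction" %in% names(tab)) tab$mitotic_fraction <- NA_real_
  fr <- c("S2", "P2", "S3", "P3")
  bad <- which(rowSums(is.na(tab[fr])) > 0 | rowSums(tab[fr] < 0) > 0)
  if (length(bad)) {
    warning("skipping ", length(bad), " invalid row(s): ",
            paste(bad, collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
  }
  if (nrow(tab) == 0) stop("no valid rows in fractionation table: ", path)
  if (values == "intensity") {
    tab[fr] <- t(apply(tab[fr], 1, normalize_fractions))
  } else {
    sums <- rowSums(tab[fr])
    off <- abs(sums - 100) > 0.5
    if (any(off)) {
      warning(sum(off), " row(s) renormalised (percents summed to != 100)")
      tab[fr][off, ] <- 100 * tab[fr][off, ] / sums[off]
    }
  }
  tab
}

#' Summarise a fractionation table with mitotic-index correction
#'
#' Aggregates replicates per protein and condition (mean +- SD, n-1
#' denominator), applies the mitotic-index correction to the G2/M
#' chromatin-pellet (P3) mean, and derives the mitotic P3 as percent of
#' control.
#'
#' @param tab data.frame from [read_fractionation_tsv()].
#' @return data.frame with one row per protein: mean/SD percentages per
#'   fraction and condition, `p3_mitotic_corrected` and
#'   `p3_percent_of_control`.
#' @export
summarize_fractionation <- function(tab) {
  fr <- c("S2", "P2", "S3", "P3")
  out <- lapply(split(tab, tab$protein), function(sub) {
    row <- data.frame(protein = sub$protein[1])
    for (cond in c("control", "G2M")) {
      s <- sub[sub$condition == cond, , drop = FALSE]
      for (f in fr) {
        row[[paste0(f, "_", cond, "_mean")]] <-
          if (nrow(s)) mean(s[[f]]) else NA_real_
        row[[paste0(f, "_", cond, "_sd")]] <-
          if (nrow(s) > 1) stats::sd(s[[f]]) else NA_real_
      }
    }
    m <- mean(tab$mitotic_fraction[tab$protein == sub$protein[1] &
                                     tab$condition == "G2M"], na.rm = TRUE)
    p3c <- row$P3_control_mean; p3g <- row$P3_G2M_mean
    row$mitotic_fraction <- m
    row$p3_mitotic_corrected <-
      if (!is.na(m) && !is.na(p3c) && !is.na(p3g)) {
        suppressWarnings(correct_mitotic_p3(p3g, p3c, m, clip = TRUE))
      } else NA_real_
    row$p3_percent_of_control <-
      if (!is.na(row$p3_mitotic_corrected) && !is.na(p3c) && p3c > 0) {
        retention_ratio(row$p3_mitotic_corrected, p3c)
      } else NA_real_
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
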