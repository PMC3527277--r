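# Single-cell colocalization of a protein channel with DNA. Masks are
# derived by Li minimum cross-entropy thresholding; the manual outline
# selection of a microscopy workflow is replaced by the thresholded
# connected component containing the global intensity maximum, with holes
# filled. The cytoplasmic mask is literally cell AND NOT DNA.

#' Li minimum cross-entropy threshold
#'
#' Iterative fixed-point form of the Li-Lee minimum cross-entropy
#' threshold: starting from the image mean, repeat
#' `t <- (mu_fg - mu_bg) / (log(mu_fg) - log(mu_bg))` where `mu_bg` and
#' `mu_fg` are the means of pixels at or below / strictly above `t`,
#' until the update moves less than `tol`. This is the minimiser of the
#' cross-entropy objective
#' `-(sum_bg * log(mu_bg) + sum_fg * log(mu_fg))` over candidate
#' thresholds. Foreground = pixels strictly above the returned value.
#'
#' @param image Numeric matrix/array of non-negative intensities with at
#'   least two distinct values.
#' @param tol Convergence tolerance in intensity units.
#' @param max_iter Iteration cap.
#' @return The threshold value.
#' @export
li_threshold <- function(image, tol = 0.5, max_iter = 200L) {
  x <- as.numeric(image)
  if (length(unique(x)) < 2) stop("constant image: no threshold exists")
  eps <- 1e-9  # guards the log terms for zero-intensity classes
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    bg <- x[x <= t_cur]; fg <- x[x > t_cur]
    if (length(bg) == 0 || length(fg) == 0) break
    mu_b <- mean(bg) + eps
    mu_f <- mean(fg) + eps
    t_new <- (mu_f - mu_b) / (log(mu_f) - log(mu_b))
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur
}

# Foreground mask refinement: connected component (8-neighbour) of the
# thresholded foreground containing the global intensity maximum, holes
# filled. Automatable proxy for manually outlining the object at the
# signal/background border.
.refine_mask <- function(image, threshold) {
  fg <- image > threshold
  if (!any(fg)) return(fg)
  lab <- EBImage::bwlabel(fg)
  peak <- which(image == max(image[fg]) & fg, arr.ind = TRUE)[1, , drop = TRUE]
  keep <- lab == lab[peak[1], peak[2]]
  filled <- EBImage::fillHull(EBImage::Image(keep * 1))
  methods::as(filled, "matrix") > 0.5
}

#' Build DNA / cell / cytoplasm masks for one cell image pair
#'
#' The DNA mask is the Li-thresholded DNA channel; the cell mask is the
#' Li-thresholded protein channel; each is reduced to the connected
#' region containing its channel's intensity maximum, holes filled. The
#' cytoplasmic mask is `cell_mask & !dna_mask`, exactly; the DNA mask is
#' not constrained to lie inside the cell mask.
#'
#' @param dna,protein Numeric matrices of equal dimensions.
#' @return List of logical matrices `dna_mask`, `cell_mask`, `cyto_mask`.
#' @export
make_masks <- function(dna, protein) {
  if (!all(dim(dna) == dim(protein))) stop("channel shapes differ")
  dna_mask <- .refine_mask(dna, li_threshold(dna))
  cell_mask <- .refine_mask(protein, li_threshold(protein))
  list(dna_mask = dna_mask, cell_mask = cell_mask,
       cyto_mask = cell_mask & !dna_mask)
}

#' Protein-on-DNA versus cytoplasmic signal ratio for one cell
#'
#' Computes the mean protein intensity within the DNA mask (`pcg_dna`)
#' and within the cytoplasmic mask (`pcg_cyto`), and their ratio — the
#' per-cell measure of chromosome colocalization.
#'
#' @param pair A list with numeric matrices `dna` and `protein` (e.g.
#'   from [simulate_cell_image()]).
#' @return List with `pcg_dna`, `pcg_cyto`, `ratio` and the `masks` used.
#'   If the cytoplasmic mask is empty the ratio is `NA` with a warning.
#' @export
colocalization_ratio <- function(pair) {
  masks <- make_masks(pair$dna, pair$protein)
  if (!any(masks$dna_mask)) stop("empty DNA mask")
  pcg_dna <- mean(pair$protein[masks$dna_mask])
  if (!any(masks$cyto_mask)) {
    warning("empty cytoplasmic mask: ratio undefined")
    pcg_cyto <- NA_real_
  } else {
    pcg_cyto <- mean(pair$protein[masks$cyto_mask])
  }
  list(pcg_dna = pcg_dna, pcg_cyto = pcg_cyto,
       ratio = pcg_dna / pcg_cyto, masks = masks)
}

#' Summarise per-cell colocalization ratios by group
#'
#' @param ratios Numeric vector of per-cell ratios.
#' @param groups Factor/character of group labels (e.g. interphase vs
#'   mitotic, extracted vs unextracted), same length.
#' @return data.frame (`group`, `mean`, `sd`, `n`); SD is `NA` for
#'   single-cell groups (n-1 denominator). Groups with no cells are
#'   omitted with a warning.
#' @export
batch_summarize <- function(ratios, groups) {
  stopifnot(length(ratios) == length(groups))
  groups <- as.factor(groups)
  empty <- setdiff(levels(groups), unique(as.character(groups[!is.na(ratios)])))
  if (length(empty)) warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  keep <- !is.na(ratios)
  res <- do.call(rbind, lapply(split(ratios[keep], droplevels(groups[keep])),
                               function(r) {
    data.frame(mean = mean(r), sd = if (length(r) > 1) stats::sd(r) else NA_real_,
               n = length(r))
  }))
  data.frame(group = rownames(res), res, row.names = NULL)
}
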