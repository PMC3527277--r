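# Synthetic-data generators. These define the study conditions the rest of
# the package is tested against: a two-condition ChIP-seq experiment in
# which a minority of binding sites persist in mitosis at reduced
# occupancy, fractionation tables under a mitotic-index mixture model, and
# two-channel cell images with known region means.

#' Simulation configuration for a two-condition ChIP-seq experiment
#'
#' The defaults emulate the statistical structure of a mitotic-bookmarking
#' ChIP-seq study: ~5,000 control binding sites of log-normally varying
#' occupancy on a small multi-chromosome genome, a 10% subset retained in
#' the "mitotic" condition at 30% of control occupancy, uniform background
#' reads, and an optional contamination of the mitotic sample by up to 5%
#' of a control-like read draw. One chromosome can be designated to lose
#' all of its sites in mitosis (total-loss arm).
#'
#' @param genome Named integer vector of chromosome lengths (bp).
#' @param n_sites Number of binding sites to plant.
#' @param site_width Width of each site in bp.
#' @param min_gap Minimum gap between adjacent sites in bp.
#' @param retained_fraction Fraction of sites retained in mitosis, in
#'   `[0, 1]`.
#' @param occupancy_scale Multiplicative occupancy factor in `(0, 1]`
#'   applied to retained sites in the mitotic condition.
#' @param occupancy_sdlog Log-sd of the log-normal site occupancy
#'   distribution (spread of peak ranks).
#' @param retention_bias Exponent weighting retention probability by
#'   occupancy (`0` = uniform; higher values concentrate retention at
#'   strong sites). The default 2 places roughly 35-40% of retained
#'   sites in the top occupancy decile, the rank dependence reported for
#'   mitotically retained Polycomb sites, while leaving retention spread
#'   across all deciles.
#' @param background_rate Uniform background read rate, reads per bp per
#'   condition.
#' @param depth Expected total signal reads per condition.
#' @param input_depth Expected reads in the signal-free input sample used
#'   for sample-swap FDR estimation.
#' @param contamination Fraction (in `[0, 0.05]`) of a control-like signal
#'   draw added to the mitotic sample, modelling interphase cells
#'   contaminating a sorted mitotic population.
#' @param equalize_depth Sequence both conditions to the same expected
#'   total depth (default TRUE). Library depth is set by the sequencer,
#'   not by how much protein is bound, so a condition with less bound
#'   signal yields proportionally more uniform background; with FALSE
#'   both conditions share the bare `background_rate`.
#' @param fragment_size Fragment length (bp) assumed when reads are
#'   extended during pileup.
#' @param border_fraction Fraction of sites flagged as lying at synthetic
#'   chromatin-domain borders (0 disables border simulation).
#' @param border_enrichment Target preferential-retention ratio for
#'   border sites: the expected (fraction of retained sites at borders) /
#'   (fraction of all sites at borders). Internally converted to the
#'   retention-weight multiplier `E(1-f)/(1-Ef)` (f = `border_fraction`),
#'   which yields that measured ratio in expectation when
#'   `retention_bias = 0`; requires `E * border_fraction < 1`.
#' @param border_width Width of emitted border intervals (bp), centred on
#'   border sites.
#' @param no_retention_chrom Chromosome whose sites are never retained
#'   (emulating total loss from one arm); `NULL` disables.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome = c(chr2L = 3e6, chr2R = 3e6, chr3L = 3e6, chr4 = 3e6),
                       n_sites = 5000,
                       site_width = 200,
                       min_gap = 300,
                       retained_fraction = 0.1,
                       occupancy_scale = 0.3,
                       occupancy_sdlog = 0.5,
                       retention_bias = 2,
                       background_rate = 5e-4,
                       depth = 50 * n_sites,
                       input_depth = depth,
                       contamination = 0,
                       equalize_depth = TRUE,
                       fragment_size = 36,
                       border_fraction = 0,
                       border_enrichment = 1,
                       border_width = 1000,
                       no_retention_chrom = "chr4",
                       seed = 1L) {
  stopifnot(length(genome) >= 1, all(genome > 0), n_sites > 0, depth > 0,
            input_depth > 0, background_rate >= 0,
            site_width >= 1, fragment_size >= 1,
            retained_fraction >= 0, retained_fraction <= 1,
            occupancy_scale > 0, occupancy_scale <= 1,
            border_fraction >= 0, border_fraction <= 1,
            border_enrichment > 0)
  if (contamination < 0 || contamination > 0.05) {
    stop("contamination must be in [0, 0.05] (sorting-purity bound)")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Place n non-overlapping sites on one chromosome with minimum gap.
.place_sites_on_chrom <- function(n, chrom_len, width, gap) {
  need <- n * width + (n - 1) * gap
  if (n > 0 && need > chrom_len) {
    stop("site generation error: ", n, " sites of ", width,
         " bp (+", gap, " bp gaps) do not fit in ", chrom_len,
         " bp; regenerate with a larger genome or fewer sites")
  }
  if (n == 0) return(integer(0))
  slack <- chrom_len - need
  u <- sort(floor(runif(n) * (slack + 1)))
  u + (seq_len(n) - 1L) * (width + gap) + 1L  # 1-based starts
}

# Draw read 5' positions for per-site signal counts. Fragment starts are
# uniform within the site; + reads report the fragment start, - reads the
# fragment end, so fragment extension in the caller reconstructs them.
.draw_site_reads <- function(sites, counts, fragment_size) {
  tot <- sum(counts)
  if (tot == 0) {
    return(GRanges(seqlengths = seqlengths(sites)))
  }
  idx <- rep.int(seq_along(sites), counts)
  lo <- start(sites)[idx]
  hi <- pmax(lo, end(sites)[idx] - fragment_size + 1L)
  frag_start <- lo + floor(runif(tot) * (hi - lo + 1))
  str <- sample(c("+", "-"), tot, replace = TRUE)
  pos <- ifelse(str == "+", frag_start, frag_start + fragment_size - 1L)
  chr_len <- seqlengths(sites)[as.character(seqnames(sites))[idx]]
  pos <- pmin(pmax(pos, 1L), chr_len)
  GRanges(seqnames(sites)[idx], IRanges(pos, width = 1L), strand = str,
          seqlengths = seqlengths(sites))
}

# Uniform background reads over the genome.
.draw_background_reads <- function(genome, n) {
  if (n == 0) return(GRanges(seqlengths = genome))
  chr <- sample(names(genome), n, replace = TRUE, prob = genome / sum(genome))
  pos <- floor(runif(n) * genome[chr]) + 1L
  GRanges(chr, IRanges(pos, width = 1L),
          strand = sample(c("+", "-"), n, replace = TRUE),
          seqlengths = genome)
}

#' Simulate a two-condition ChIP-seq experiment with known truth
#'
#' Plants non-overlapping sites, assigns log-normal occupancies, selects a
#' retained subset (biased towards high occupancy by
#' `retention_bias`, and towards border sites by `border_enrichment`),
#' then draws Poisson read counts per site: control signal with mean
#' `depth * occupancy_share`, mitotic signal only at retained sites with
#' the occupancy scaled by `occupancy_scale`, plus uniform background in
#' both conditions, an optional control-like contamination draw in the
#' mitotic sample, and a signal-free input sample for FDR estimation.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `chip_simulation` with elements `control`,
#'   `mitotic`, `input` (ReadSets), `sites` (`GRanges` with truth columns
#'   `site_id`, `occupancy`, `retained`, `at_border`,
#'   `expected_reads_control`, `expected_reads_mitotic`), `borders`
#'   (`GRanges`, empty unless `border_fraction > 0`), and `config`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- cfg$genome

  # Allocate sites to chromosomes proportionally to length, then place.
  chrom <- sample(names(genome), cfg$n_sites, replace = TRUE,
                  prob = genome / sum(genome))
  starts <- integer(0); chroms <- character(0)
  for (chr in names(genome)) {
    n_c <- sum(chrom == chr)
    s <- .place_sites_on_chrom(n_c, genome[[chr]], cfg$site_width, cfg$min_gap)
    starts <- c(starts, s)
    chroms <- c(chroms, rep(chr, n_c))
  }
  sites <- GRanges(chroms, IRanges(starts, width = cfg$site_width),
                   seqlengths = genome)
  sites <- sort_intervals(sites)

  occ <- rlnorm(cfg$n_sites, meanlog = 0, sdlog = cfg$occupancy_sdlog)
  share <- occ / sum(occ)

  at_border <- rep(FALSE, cfg$n_sites)
  borders <- GRanges(seqlengths = genome)
  if (cfg$border_fraction > 0) {
    nb <- round(cfg$border_fraction * cfg$n_sites)
    at_border[sample.int(cfg$n_sites, nb)] <- TRUE
    borders <- .extend_trim(sites[at_border], cfg$border_width, fix = "center")
  }

  eligible <- rep(TRUE, cfg$n_sites)
  if (!is.null(cfg$no_retention_chrom)) {
    eligible <- !(as.character(seqnames(sites)) %in% cfg$no_retention_chrom)
  }
  n_ret <- round(cfg$retained_fraction * cfg$n_sites)
  n_ret <- min(n_ret, sum(eligible))
  retained <- rep(FALSE, cfg$n_sites)
  if (n_ret > 0) {
    w_border <- 1
    if (cfg$border_fraction > 0 && cfg$border_enrichment != 1) {
      ef <- cfg$border_enrichment * cfg$border_fraction
      if (ef >= 1) {
        stop("border_enrichment x border_fraction must be < 1")
      }
      w_border <- cfg$border_enrichment * (1 - cfg$border_fraction) / (1 - ef)
    }
    w <- occ^cfg$retention_bias * ifelse(at_border, w_border, 1)
    w[!eligible] <- 0
    retained[sample.int(cfg$n_sites, n_ret, prob = w)] <- TRUE
  }

  mu_control <- cfg$depth * share
  mu_mitotic <- cfg$depth * share * cfg$occupancy_scale * retained

  n_control <- rpois(cfg$n_sites, mu_control)
  n_mitotic <- rpois(cfg$n_sites, mu_mitotic)

  ctl_sig <- .draw_site_reads(sites, n_control, cfg$fragment_size)
  mit_sig <- .draw_site_reads(sites, n_mitotic, cfg$fragment_size)

  if (cfg$contamination > 0) {
    n_contam <- rpois(cfg$n_sites, cfg$depth * share * cfg$contamination)
    mit_sig <- c(mit_sig, .draw_site_reads(sites, n_contam, cfg$fragment_size))
  }

  bg_expect <- cfg$background_rate * sum(genome)
  if (cfg$equalize_depth) {
    # both libraries sequenced to the same expected total depth; the
    # condition with less bound signal gets proportionally more background
    total_depth <- cfg$depth + bg_expect
    mu_sig_mit <- sum(mu_mitotic) + cfg$contamination * cfg$depth
    bg_mu <- c(control = bg_expect,
               mitotic = max(bg_expect, total_depth - mu_sig_mit))
  } else {
    bg_mu <- c(control = bg_expect, mitotic = bg_expect)
  }
  n_bg <- rpois(2, bg_mu)
  ctl <- sort_intervals(c(ctl_sig, .draw_background_reads(genome, n_bg[1])))
  mit <- sort_intervals(c(mit_sig, .draw_background_reads(genome, n_bg[2])))
  inp <- sort_intervals(.draw_background_reads(genome, rpois(1, cfg$input_depth)))

  mcols(sites) <- DataFrame(site_id = sprintf("site_%05d", seq_len(cfg$n_sites)),
                            occupancy = occ, retained = retained,
                            at_border = at_border,
                            expected_reads_control = mu_control,
                            expected_reads_mitotic = mu_mitotic)
  structure(list(control = read_set(ctl),
                 mitotic = read_set(mit),
                 input = read_set(inp),
                 sites = sites, borders = borders, config = cfg),
            class = "chip_simulation")
}

#' @export
print.chip_simulation <- function(x, ...) {
  cat("chip_simulation:", length(x$sites), "sites (",
      sum(mcols(x$sites)$retained), "retained );",
      length(x$control), "control /", length(x$mitotic), "mitotic /",
      length(x$input), "input reads\n")
  invisible(x)
}

#' Simulate a subcellular-fractionation measurement
#'
#' The observed G2/M percentages are the mitotic-index mixture
#' `(1 - m) * control + m * mitotic` of the true per-fraction percentage
#' vectors, plus Gaussian measurement noise; the control condition is
#' observed with the same noise. Truth is returned so recovery via the
#' mitotic-index correction can be tested.
#'
#' @param true_control,true_mitotic Numeric 4-vectors of true percentages
#'   for fractions S2, P2, S3, P3; each must sum to 100 (+- 0.01).
#' @param mitotic_fraction Mitotic index m in `(0, 1]` of the G2/M
#'   population.
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param seed Integer seed.
#' @return A list of class `fractionation_sim` with `control`, `g2m`
#'   (observed named vectors), `mitotic_fraction`, and `truth`.
#' @export
simulate_fractionation <- function(true_control, true_mitotic,
                                   mitotic_fraction, noise_sd = 0, seed = 1L) {
  fr <- c("S2", "P2", "S3", "P3")
  for (v in list(true_control, true_mitotic)) {
    if (length(v) != 4L) stop("fraction vectors must have 4 entries (S2, P2, S3, P3)")
    if (abs(sum(v) - 100) > 0.01) {
      stop("fraction percentages must sum to 100 (+-0.01), got ", sum(v))
    }
  }
  if (mitotic_fraction <= 0 || mitotic_fraction > 1) {
    stop("mitotic_fraction must be in (0, 1]")
  }
  set.seed(seed)
  m <- mitotic_fraction
  g2m <- (1 - m) * true_control + m * true_mitotic + rnorm(4, 0, noise_sd)
  ctl <- true_control + rnorm(4, 0, noise_sd)
  structure(list(control = setNames(as.numeric(ctl), fr),
                 g2m = setNames(as.numeric(g2m), fr),
                 mitotic_fraction = m,
                 truth = list(control = setNames(as.numeric(true_control), fr),
                              mitotic = setNames(as.numeric(true_mitotic), fr))),
            class = "fractionation_sim")
}

#' Simulate a two-channel cell image with known region means
#'
#' Builds a circular cell containing a concentric circular nucleus on a
#' square field. The DNA channel is bright only in the nucleus; the
#' protein channel has the configured mean in nucleus, cytoplasm (cell
#' minus nucleus) and background. Truth masks are returned.
#'
#' @param nucleus_mean,cyto_mean,background_mean Protein-channel means in
#'   the nucleus, cytoplasm and background (arbitrary intensity units).
#' @param dna_nucleus_mean,dna_background_mean DNA-channel means.
#' @param size Image side length in pixels.
#' @param cell_radius,nucleus_radius Radii in pixels; the nucleus must lie
#'   strictly inside the cell.
#' @param noise_sd Gaussian noise SD added to both channels (clamped at 0).
#' @param seed Integer seed.
#' @return A list of class `cell_image_pair` with matrices `dna`,
#'   `protein` and logical truth masks `nucleus_mask`, `cell_mask`.
#' @export
simulate_cell_image <- function(nucleus_mean = 300, cyto_mean = 100,
                                background_mean = 5,
                                dna_nucleus_mean = 400,
                                dna_background_mean = 5,
                                size = 96, cell_radius = 36,
                                nucleus_radius = 16,
                                noise_sd = 0, seed = 1L) {
  if (nucleus_radius >= cell_radius) {
    stop("image generation error: nucleus must lie strictly inside the cell")
  }
  if (cell_radius >= size / 2) {
    stop("image generation error: cell does not fit in the field")
  }
  stopifnot(nucleus_mean >= 0, cyto_mean >= 0, background_mean >= 0)
  set.seed(seed)
  ctr <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  nucleus_mask <- d <= nucleus_radius
  cell_mask <- d <= cell_radius
  protein <- matrix(background_mean, size, size)
  protein[cell_mask] <- cyto_mean
  protein[nucleus_mask] <- nucleus_mean
  dna <- matrix(dna_background_mean, size, size)
  dna[nucleus_mask] <- dna_nucleus_mean
  if (noise_sd > 0) {
    protein <- pmax(protein + rnorm(length(protein), 0, noise_sd), 0)
    dna <- pmax(dna + rnorm(length(dna), 0, noise_sd), 0)
  }
  structure(list(dna = dna, protein = protein,
                 nucleus_mask = nucleus_mask, cell_mask = cell_mask),
            class = "cell_image_pair")
}
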