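---
title: "Methods: quantifying mitotic retention of a chromatin protein"
author: "bookmarkR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitotic retention of a chromatin protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bookmarkR)
library(GenomicRanges)
```

## The question and the measurement model

During mitosis most sequence-specific chromatin proteins are displaced
from condensed chromosomes, yet some remain bound at a subset of their
interphase sites ("mitotic bookmarking"). Deciding whether an apparent
mitotic binding site is real is harder than it sounds, because a sorted
mitotic cell population is never perfectly pure: a few percent of
interphase cells carry their full binding signal into the mitotic
sample, and a few percent of a strong interphase peak can look exactly
like a weak retained peak.

`bookmarkR` implements the complete computational path for this
question across three independent assays:

1. **Two-condition ChIP-seq.** Peaks are called separately in a control
   (interphase-dominated) and a mitotic sample with a minimal
   MACS-style caller; control peaks are classified as *persistent*
   (overlapping a mitotic peak) or *control-only*, retention is
   profiled by control-peak rank decile, and two contamination
   controls — an aggregate profile null and a per-peak carry-over
   test — guard against sorting impurity.
2. **Subcellular fractionation.** Western-blot band percentages over
   the fractions S2 (cytosol), P2, S3 (soluble nuclear) and P3
   (chromatin pellet) are corrected for the mitotic index of a G2/M
   culture and expressed as percent of the control chromatin fraction.
3. **Immunofluorescence colocalization.** Per-cell ratios of mean
   protein intensity on DNA versus in the cytoplasm, with masks derived
   by Li minimum cross-entropy thresholding.

Every stage can be exercised on synthetic data with known truth; the
generators are first-class, tested package code.

## The peak caller

The caller is intentionally the simplest procedure consistent with the
standard parameterisation of a single-end, fixed-fragment ChIP-seq
analysis:

* Each read contributes a pseudo-fragment of `fragment_size` bp
  (default 36) downstream of its 5' end (upstream for minus-strand
  reads), clipped at chromosome edges. There is no shift-model
  estimation: the fragment size is treated as a known constant, so the
  pileup conserves mass exactly (`sum(coverage) = reads x fragment -
  clipping`), which the tests assert.
* Windows of `bandwidth` bp (default 200) slide at half-bandwidth
  steps. The number of fragments overlapping a window of width $w$ is
  Poisson with mean $\lambda = r\,(w + f - 1)$ under a uniform
  background of $r$ fragment starts per bp, since a fragment of length
  $f$ overlaps the window iff its start falls in a span of $w + f - 1$
  bp. Windows with upper-tail $P(X \ge k) <$ `p_cutoff` (default
  $10^{-5}$) are merged when within one bandwidth of each other.
* Each merged region is re-scored as one peak: fragment count,
  maximum pileup (height), fold over the expected background pileup,
  and a Poisson p-value at the region's own width. The region must
  itself meet the p-value cutoff — merging marginal windows cannot
  rescue a peak. When an input/control track is available, the
  background rate is the maximum of the genome-wide rate and
  depth-scaled local rates estimated from the control in 1-kb and
  10-kb windows (the usual local-lambda convention).
* The summit is the median position of the maximum plateau of the
  pileup smoothed by a moving average of half the bandwidth. At
  realistic depths (tens of reads per site) the raw per-bp argmax is a
  sampling spike; smoothing at the caller's own scale parameter
  restores summit accuracy to within ±50 bp of true site centres in
  ≥95% of simulated sites, which is the bar the tests enforce.
* Significant peaks are filtered by **sample-swap empirical FDR**: for
  each treatment peak with p-value $p$, `fdr = #\{swap peaks \le p\} /
  #\{treatment peaks \le p\}`, where swap peaks come from calling with
  treatment and control exchanged. The raw ratio is not guaranteed
  monotone along the p-value ranking, so a running maximum (the same
  step-up smoothing used for q-values) is applied before filtering at
  5%. Without a control sample the FDR is undefined; the caller then
  reports `NA` and falls back to the p-value cutoff, with a message.

Numerical notes: p-values are floored at `.Machine$double.xmin` so
downstream `-log10` transforms are finite; ties in p-value are broken
by fragment count and then coordinate, making every output
deterministic.

## Retention statistics

A control peak is *persistent* when it shares at least `min_bp` (default
1 bp, the conventional any-overlap rule) with a mitotic peak. A mitotic
peak overlapping several control peaks is assigned to the one with the
largest intersection, ties to the better p-value — the least surprising
rule where no convention exists; it is parameterised. The decile table
ranks control peaks best-first by p-value, fragment count, height or
fold, splits them into ten equal bins (remainder spread over the leading
bins, deterministically), and reports the percentage of partnered
mitotic peaks per bin. Profile similarity between conditions is the
Pearson correlation of per-peak fragment counts over the merged union of
both peak sets.

## The two contamination controls

Suppose a fraction $c \le 0.05$ of the sorted "mitotic" cells are
actually interphase cells. Then every interphase peak appears in the
mitotic sample scaled by roughly $c$ — qualitatively the same picture as
genuine retention at reduced occupancy. Two complementary checks
address this:

* **Aggregate null (profile level).** The average mitotic profile over
  peak regions is compared with the profile of a 5% binomial subsample
  of the control reads *in those regions*, kept on the control
  sample's RPM scale. Keeping the parent `total_mapped` as the
  denominator is deliberate: the null models a small admixture inside
  a library sequenced at full depth, and renormalising by the
  subsampled count would cancel the effect being tested. The headline
  statistic is the ratio of central enrichment (mean RPM within ±200
  bp of the anchor, minus each profile's own flanking baseline).
  Baseline subtraction matters because the mitotic library carries a
  genome-wide background floor that the in-region subsample lacks by
  construction; without it the ratio is biased upward by the
  background alone. Pure contamination gives a ratio near 1; genuine
  retention at 30% occupancy gives ratios of 5 and above in the
  simulations.
* **Per-peak carry-over test.** Each candidate mitotic peak's fragment
  count is compared against a Poisson null with mean `fraction x
  (control fragments at that locus) x (depth ratio) + (mitotic
  background expectation in the peak)`; peaks whose
  Benjamini-Hochberg-adjusted upper-tail probability is below
  `contamination_alpha` (default 0.01) are kept. A true retained site
  at ~30% of its control occupancy is roughly six-fold above this
  null and passes easily; a 5% carry-over peak does not. The filter is
  applied by `run_retention()` and can be disabled
  (`contamination_alpha = NA`). Peaks at loci where the mitotic count
  is a strong upward fluctuation of the carry-over null remain
  genuinely indistinguishable from weak retention — no per-peak test
  can separate a 9-read fluctuation from a 10-read-expected retained
  site — and this residual error is visible in the simulation results
  rather than hidden.

## The synthetic experiment

`sim_config()` defaults define the study conditions and are not tuned
per test:

* Genome: four 3-Mb chromosomes. 5,000 non-overlapping 200-bp sites
  are placed with ≥300 bp gaps, allocated to chromosomes by length;
  sites on the fourth chromosome are never retained, emulating an arm
  that loses all its sites in mitosis.
* Occupancies are log-normal (sdlog 0.5) so peak ranks are
  non-degenerate; the real occupancy distribution of Polycomb sites is
  unknown and this is a modelling convenience.
* 10% of sites are retained at 30% of control occupancy. Retention is
  biased towards strong sites with weight `occupancy^2`: that exponent
  places roughly 35–40% of retained sites in the top occupancy decile,
  matching the reported rank dependence of mitotically retained
  Polycomb sites, while leaving retention spread over all deciles.
* Mean signal depth is 50 reads per site; uniform background is
  5 x 10^-4 reads/bp. Both conditions are sequenced to the same
  expected total depth (`equalize_depth = TRUE`): library depth is a
  property of sequencing, not of how much protein is bound, so the
  mitotic sample — with ~97% less bound signal — has proportionally
  more background. This matters: the mitotic sample's own background
  sets the caller's detection threshold, and a generator that let the
  mitotic library shrink to its signal would make single-digit
  carry-over read piles look hugely significant.
* Contamination adds an independent Poisson draw with mean `c x
  depth x occupancy share` at every site (bounded at 5%, the stated
  sorting purity). A signal-free input sample of matching depth is
  generated for sample-swap FDR.
* Optionally, a fraction of sites is flagged as chromatin-domain
  borders. `border_enrichment` is parameterised as the *measured*
  preferential-retention ratio (mitotic border fraction over control
  border fraction); it is converted internally to the weight
  multiplier `E(1-f)/(1-Ef)`, exact in expectation for unbiased
  retention and approximate when occupancy bias is also active.

All generators are pure functions of `(config, seed)`; byte-identical
reruns are asserted by the tests.

What passing on this synthetic data does **not** show: real ChIP-seq
has non-uniform mappability and chromatin-accessibility background,
PCR duplicates, fragment-size variation, and antibody-specific
cross-reactivity. None of these are modelled; conclusions about the
pipeline's statistical behaviour transfer to real data only to the
extent that the local-lambda control absorbs such structure.

## Fractionation correction

A colchicine-arrested G2/M culture is only 60–70% mitotic. With mitotic
index $m$, the observed chromatin-pellet percentage is the mixture
$P3_{G2M} = (1 - m)\,P3_{control} + m\,P3_{mitotic}$, inverted by

$$P3_{mitotic} = \frac{P3_{G2M} - (1 - m)\,P3_{control}}{m}.$$

The correction is applied to P3 as printed; a negative result means
noise exceeded the mixture model and is reported with a warning, not
silently clipped (clipping applies only to the exported summary table).
Replicate aggregation uses the n−1 standard deviation. Retention is
expressed as `100 x corrected / control`; for the positive-control
protein in the worked example (corrected G2/M P3 = 8%, control P3 =
43%) this gives 18.6%, matching the printed "18%" within integer
rounding. The tests verify the inversion to machine precision over a
grid of true values, controls and mitotic indices.

## Image colocalization

The Li minimum cross-entropy threshold is computed by the standard
fixed-point iteration `t <- (mu_fg - mu_bg) / (log mu_fg - log mu_bg)`
started from the image mean, with a small epsilon guarding the log
terms; an exhaustive minimisation of the cross-entropy objective over
all candidate thresholds serves as the independent oracle in the tests
(agreement within one intensity level on 100 random bimodal images).
Masks replace the manual outline selection of an interactive workflow
with the thresholded connected component containing the channel's
global maximum, holes filled — a documented deviation that makes the
procedure automatable. The cytoplasmic mask is literally `cell & !dna`;
the DNA mask is not constrained to lie inside the cell mask, so the
subtraction is exactly as stated. The per-cell statistic is
`pcg_dna / pcg_cyto`, the ratio of mean protein intensity over the DNA
mask versus the cytoplasmic mask; on a noise-free synthetic cell with
nucleus mean 300 and cytoplasm mean 100 it returns exactly 3.0.

## Pipeline determinism and problem sizes

`run_retention()` writes peaks, retention sets, the decile table,
profiles, the contamination summary, overlap and distribution tables,
and a timestamp-free JSON manifest of all effective parameters, so two
runs with the same config and seed are byte-identical — asserted
file-by-file in the tests. Default parameters follow the conventional
values for this analysis (fragment 36 bp, bandwidth 200 bp, $P <
10^{-5}$, 5% FDR, 50-bp bins, ±2-kb TSS windows, 5-Mbp distribution
windows, chrU/chrUextra dropped); the effective genome size defaults to
the supplied genome's total length, with 1.2e8 bp the conventional
choice for fly data.

The shipped test-suite simulations use 100–1,000 sites on 1–12 Mb toy
genomes with 50 reads per site — sizes chosen so each property is
measured with comfortable statistical margin while the whole suite runs
in about two minutes. The same code paths scale linearly in reads and
windows for genome-scale inputs.

## Known limitations

* The caller targets sharp binding sites; broad domains and paired-end
  data are out of scope.
* The per-peak carry-over filter assumes the contamination bound is
  known (it is an input, default 5%); an underestimated bound weakens
  the filter.
* `border_enrichment` is exact in expectation only when retention is
  otherwise unbiased; combined with occupancy bias the realised ratio
  drifts slightly below the target.
* The image module quantifies one cell per field (single connected
  component); crowded fields need external segmentation first.
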