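# bookmarkR

Tools for deciding whether a chromatin protein stays bound to mitotic
chromosomes at specific sites ("mitotic bookmarking"), written for
epigenomics analysts comparing a control (interphase-dominated) and a
mitotic ChIP-seq sample, with companion assays for subcellular
fractionation and immunofluorescence colocalization.

The central difficulty is that a FACS-sorted mitotic population carries
up to ~5% interphase cells, and 5% of a strong interphase peak can look
exactly like a weak retained peak. `bookmarkR` therefore combines:

* a minimal **Poisson local-background peak caller** (fixed fragment
  extension *f*, sliding windows of bandwidth *w*, upper-tail
  `P(X >= k)` at `lambda = r (w + f - 1)`, local lambda from an input
  track, sample-swap empirical FDR at 5%);
* **retention classification** of control peaks into persistent /
  control-only sets, decile retention by peak rank (p-value, reads,
  height, fold over background), and Pearson correlation of per-peak
  read counts;
* two **contamination controls**: an aggregate profile null built from
  a 5% subsample of control reads in peak regions (kept on the control
  RPM scale), and a per-peak Poisson carry-over test;
* **annotation** against chromatin-domain borders, insulator sets and
  TSS tables (±2 kb), plus per-chromosome and 5-Mbp-window
  distribution comparisons;
* the **mitotic-index correction** for fractionation westerns,
  `P3_mitotic = (P3_G2M - (1 - m) P3_control) / m`, with replicate
  aggregation and percent-of-control output;
* **Li minimum cross-entropy thresholding** and `PcG_DNA / PcG_cyto`
  colocalization ratios for two-channel cell images;
* a **synthetic-data generator** with known truth (site occupancies,
  retained subset, contamination, borders, fractionation mixtures,
  cell images) so that every stage is testable end to end without any
  external data.

## Worked example

Simulate a two-condition experiment (1,000 sites, 10% retained at 30%
occupancy, 5% interphase contamination) and run the full retention
analysis:

```r
library(bookmarkR)

cfg <- sim_config(n_sites = 1000, contamination = 0.05, seed = 1)
sim <- simulate_experiment(cfg)
sim
#> chip_simulation: 1000 sites ( 100 retained ); 56279 control / 56172 mitotic / 49862 input reads

res <- run_retention(sim$control, sim$mitotic, sim$input, cfg$genome,
                     "retention_out", config = pipeline_config(seed = 1))
res$retention
#> retention_result: 98 persistent, 884 control-only, 0 mitotic-only peaks

round(res$deciles[, "n_reads"], 1)
#>  [1] 34.7 19.4 16.3  2.0  5.1  7.1  2.0  8.2  3.1  2.0

res$contamination
#> contamination_check: central-bin mitotic / subsampled-control ratio = 6.65

round(res$correlation, 3)
#> [1] 0.595
```

Reading the output: of 982 control peaks, 98 persist in mitosis and
they recover the 100 planted retained sites almost exactly (no
mitotic-only peaks survive the 5% FDR and the carry-over filter).
Retention concentrates in the top rank deciles (34.7% of mitotic peaks
pair with top-decile control peaks) without being confined to them,
and the mitotic central enrichment is ~6.7x what 5% interphase
carry-over could produce, so the retained peaks are not a sorting
artifact.

The companion assays are one call each:

```r
retention_ratio(8, 43)       # chromatin-pellet P3, percent of control
#> [1] 18.60465

cell <- simulate_cell_image(nucleus_mean = 300, cyto_mean = 100, noise_sd = 0)
colocalization_ratio(cell)$ratio
#> [1] 3
```

A thin command-line front end over the same functions is installed at
`inst/scripts/bookmark-pipeline.R` (subcommands `simulate`,
`retention`, `fractionation`).

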