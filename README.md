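# bivalseq

Genome-wide analysis of **bivalent chromatin at mononucleosome
resolution** from sequential (re-)ChIP-seq, together with a fully
parameterized simulator of the cell-population chromatin model the
analysis assumes.

Bivalent chromatin is the co-occurrence of the activating H3K4me3 and the
repressive H3K27me3 marks at a promoter. Classical single-mark ChIP-seq
can only show that the two marks *zonally* overlap in a cell population;
it cannot tell whether any single nucleosome carries both marks, or
whether different cells carry one mark each. Sequential ChIP
(1° anti-H3K27me3 → 2° anti-H3K4me3) of MNase-derived mononucleosomes
resolves this, at the price of very sparse, noisy libraries that need
careful input normalization and controls against primary-IP
flow-through. `bivalseq` implements that full analysis path for R users:

* **Island calling** — a SICER-style windowed caller for narrow
  (H3K4me3, gap 600 bp) and broad (H3K27me3, gap 1000 bp) marks:
  200-bp windows, fragment size 200 bp, effective genome fraction 0.75,
  Poisson window eligibility, gapped island assembly, per-island Poisson
  tests against a scaled control with Benjamini–Hochberg FDR (q ≤ 0.01).
* **Promoter classification** — bivalent / H3K4me3-exclusive /
  H3K27me3-exclusive / none, from island calls in ±2500 bp (or ±5000 bp)
  around each TSS, with overlap-zone geometry summaries.
* **Profiles** — TSS-anchored, strand-oriented, 10-bp-binned
  fragment-coverage matrices, averaged per promoter class and normalized
  to the matching input average; size-scaled enhancer profiles
  (10 body intervals + 5-kb flanks) and width-matched random controls.
* **Stratification** — CpG-island promoters (±1500 bp) with density
  quintiles, expression quintiles on log2 intensities, and Infinium-style
  methylation classes (methylated if any probe β ≥ 0.75, unmethylated if
  all β < 0.25, detection p ≤ 0.05).
* **Simulator** — a miniature genome in which each promoter archetype
  (bivalent, K4-only, K27-only, silenced-methylated, none) gets phased
  147-bp nucleosomes, zonal mark domains, a nucleosome-depleted region,
  and — only on TSS-proximal copies — true double-marking at a
  controllable rate `f_biv`, with population heterogeneity, IP capture
  efficiencies `eps1`/`eps2`, flow-through rate `phi`, and Poisson
  background. Every pipeline stage can therefore be checked against
  known ground truth.

The key model quantities: for each TSS-proximal nucleosome copy in a
cell, P(both marks) = `f_biv`; the sequential-ChIP sampling weight of a
copy is `eps1·eps2` if it carries both marks, `phi·eps2` if it carries
H3K4me3 alone (carryover), and 0 otherwise. Zonal domains co-occur
without co-occupancy, which is exactly the distinction the assay exists
to make.

## Worked example

```r
library(bivalseq)

cfg <- demo_config(seed = 42, n_genes = 80, depth = 1e5)
res <- run_pipeline(cfg, outdir = "demo_out")

glance(res$islands$k4)
#>   n_islands median_width total_span median_q
#> 1        40         2400     103200        0
glance(res$islands$k27)
#>   n_islands median_width total_span median_q
#> 1        56         4600     217200        0
glance(res$classes)
#>   bivalent K4_exclusive K27_exclusive  none
#> 1       20           20            20    20
res$summary$archetype_recovery
#> [1] 1
res$summary$overlap_zone_width
#> $min 200   $median 1000   $max 2400
p <- res$profiles[["bivalent.seqchip"]]
p$offset[which.max(p$value)]
#> [1] 120
```

Reading the numbers: the H3K4me3 islands are narrower (median 2.4 kb)
than the H3K27me3 islands (median 4.6 kb), and the K4×K27 overlap zones
are narrower still (median 1.0 kb) — the size ordering expected of a
narrow mark inside a broad upstream-shifted domain. All 80 simulated
archetypes are recovered by classification, and the input-normalized
sequential-ChIP profile over bivalent promoters peaks 120 bp from the
TSS: bivalency is focal at the TSS even though the single-mark domains
overlap over kilobases. `autoplot()` on any profile, and
`plot_island_widths(K4me3 = res$islands$k4, K27me3 = res$islands$k27)`,
draw the corresponding figures.

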