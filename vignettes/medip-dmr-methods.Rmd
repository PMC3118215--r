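---
title: "Calling tissue- and stage-specific DMRs from MeDIP promoter + CpG-island arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue- and stage-specific DMRs from MeDIP promoter + CpG-island arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
library(dplyr)
```

## The measurement and the model

Methylated-DNA immunoprecipitation (MeDIP) enriches 5-methyl-cytosine-bearing
DNA fragments with an antibody; co-hybridising immunoprecipitated and input
DNA on a two-colour tiling array gives a per-probe log2 IP/input ratio that is
elevated wherever the underlying fragment population is methylated. The array
family this package targets tiles all RefSeq promoters and all annotated CpG
islands (CpGi) of a genome at roughly 50–100 bp probe spacing, plus a few
megabase-scale contiguous tiling regions; everything else is uncovered.

The analysis chain is:

1. **Scaling.** Each replicate's log2 ratios are centred by subtracting the
   array-wide Tukey biweight mean (`biweight_mean()`, tuning constant
   `c = 5`, median/MAD initialisation, MAD held fixed across iterations). The
   biweight is used instead of the arithmetic mean because enriched probes
   form a heavy right tail that would otherwise drag the centre upward.
2. **P scores.** For every probe, the scaled ratios of the probes whose
   centres fall inside a fixed 750-bp window around the focal probe's centre
   are compared with the rest of the array by a one-sided Kolmogorov–Smirnov
   test. The statistic is `D+ = max_x [ECDF_bg(x) − ECDF_win(x)]` (clamped at
   zero), evaluated at all pooled data points with right-continuous ECDFs, so
   ties are handled deterministically. The asymptotic one-sided p-value
   `exp(−2 D+² m n / (m+n))` is clipped to `[1e-300, 1]` and reported as the
   P score `−log10 p`. Windows with fewer than two probes score 0.
3. **Peaks.** Raw methylation peaks are maximal runs of at least two
   consecutive probes with P ≥ 2; peaks whose edges are within 500 bp
   (inclusive) are merged. A sample's **consensus peak** is the region shared
   by its two biological replicates: pairwise intersections of overlapping
   raw peaks, dropped when they contain fewer than two probe centres, then
   unioned.
4. **Partition and presence patterns.** The consensus peaks of all samples
   under comparison are cut at every peak boundary into atomic sub-regions;
   per atom each sample is *present* (consensus coverage), *absent* (no raw
   peak of either replicate overlaps — the raw-peak veto makes "unmethylated"
   a strong claim), or *ambiguous* (raw evidence in one replicate only).
   Ambiguous records are kept but flagged and excluded from headline counts,
   which makes every differential count deliberately conservative.
5. **Classification.** Across the four adult tissues a region methylated in
   at least one and unmethylated in at least one is a tissue-specific DMR
   (T-DMR): tissue-unique or multi-tissue. Within one tissue across the
   stages E15 → newborn → adult, the analogous object is a stage-specific DMR
   (DS-DMR) with six differential patterns, grouped into UnMe-AD (methylated
   early, unmethylated in adult — developmental demethylation) and Me-AD
   (methylated in adult — de novo methylation).
6. **Location categories.** Each DMR gets exactly one category, tried in
   priority order: CpGi promoter (within 500 bp of an island *and* inside a
   TSS ± 1 kb promoter), non-CpGi promoter, intragenic CpGi (near an island
   overlapping a gene body, the gene span minus that gene's own promoter
   window), intergenic CpGi (near an island more than 2 kb from every gene
   span). Anything matching none of the four falls through to non-CpGi
   intragenic/intergenic — categories that on the real array only arise in
   the contiguous tiling regions (`strict_tiling = TRUE` enforces that
   restriction and leaves other fall-throughs `NA`).
7. **Tabulation.** `tabulate_dmrs()` produces the pattern × category count
   tables with per-row percentages; `cross_tissue_overlap()` reports, for the
   per-tissue DS-DMR sets, both the with-multiplicity total and the
   de-duplicated total after single-linkage clustering of overlapping
   regions; `adjust_counts()` rescales pattern counts for unequal replicate
   concordance; `shore_density()` compares DMR density per bp inside CpG
   islands with their 2-kb shores.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `window_bp` | 750 | bp | total KS window span; the method's spatial resolution |
| `pscore_threshold` | 2 | −log10 p | probe qualifies at p ≤ 0.01 |
| `min_consecutive_probes` | 2 | probes | single-probe spikes are not peaks |
| `merge_bp` | 500 | bp | edge gap at or below this merges peaks (inclusive) |
| `promoter_flank_bp` | 1000 | bp | promoter = TSS ± 1 kb, strand-aware |
| `cpgi_proximity_bp` | 500 | bp | "near a CpG island", edge-to-edge |
| `intergenic_min_bp` | 2000 | bp | island-to-gene clearance for "intergenic" |
| `shore_bp` | 2000 | bp | CpGi shore width per side |
| `min_subpeak_probes` | 2 | probes | floor for consensus slivers and partition atoms |
| `max_probe_gap_bp` | Inf | bp | break probe runs across uncovered gaps |

All coordinates are 0-based half-open internally; file dialects (GFF
1-based-inclusive, BED/refFlat/cpgIslandExt 0-based) are converted at the I/O
boundary only. Distances are edge-to-edge, zero when intervals touch,
infinite across chromosomes; "within 500 bp" means distance ≤ 500.

Choices made where the upstream convention is unpublished, all exposed in
`medip_config()`:

* The biweight tuning constant (5.0) and its fixed-MAD iteration are a
  convention; commercial implementations do not document theirs.
* The KS p-value is the asymptotic closed form; the exact small-sample
  p-value serves only as a test oracle (the two rank identically in the
  statistic, which is all a fixed threshold consumes).
* The background is the whole array minus the window (`ks_background =
  "exclude"`); `"all"` is available for compatibility experiments.
* "Consecutive probes" means adjacent in array order. On layouts with long
  uncovered gaps we run with `max_probe_gap_bp = window_bp` (750 bp): probes
  farther apart than one window can never co-occur in a scoring window, and
  letting a run bridge a multi-kilobase uncovered gap would manufacture peaks
  with no probe support in between. The package default remains unlimited
  because covered regions on the real array are locally dense.
* Consensus intersections and partition atoms need ≥ 2 probes, mirroring the
  2-probe peak floor; this prevents 1-bp sliver regions.
* The concordance adjustment (`adjust_counts()`) — per-stage factor
  `r_best / r_s` on P-score concordance, geometric mean across a pattern's
  member stages, rounded — is this package's declared rule. The upstream
  computation behind published "adjusted" columns is not recoverable, so
  these values should be read as a sensitivity check, not as calibrated
  estimates.

## What the synthetic generator emulates — and what it does not

`simulate_experiment()` builds a complete ground-truthed experiment:
non-overlapping genes on a small genome (default 200 genes on 2 × 4 Mb), a
configurable fraction (default 0.685) with a promoter CpG island plus
intragenic and intergenic islands, probes tiling promoters, island
neighbourhoods and one 60-kb contiguous tiling region at 100-bp spacing, and
a 4-tissue × 3-stage × 2-replicate sample design.

Truth regions are runs of 8–15 consecutive probes (≈0.75–1.5 kb), *snapped to
probe boundaries* so that truth/call comparison is exact. Two geometric
constants are derived from the method rather than chosen freely: regions span
at least one 750-bp scoring window, because any region shorter than the
window dilutes every window that covers it and is systematically missed — it
is below the method's resolution, and benchmarking recovery on
sub-resolution regions would measure the simulator, not the pipeline; and
consecutive truth regions are separated by more than `merge_bp + window_bp`
(14 probes), because window-edge bleed plus the 500-bp merge can bridge
anything closer. Methylated probes get a log2-ratio shift of `mu_me = 1.5`
over noise `sigma = 0.4` — the clear-enrichment regime of a two-colour MeDIP
array — and replicate correlation is controlled analytically by splitting the
noise into a shared component (`sd = sigma * sqrt(rho)`) and a per-replicate
component (`sd = sigma * sqrt(1 − rho)`), `rho = 0.85`, the upper half of the
0.68–0.88 replicate-concordance range typical for this assay. Presence
patterns are drawn as: 10% common to all samples, 30% tissue-unique across
all stages, 40% stage-subsets within one tissue, 20% multi-tissue.

The generator does **not** model CpG-density-dependent MeDIP efficiency
(real MeDIP under-enriches low-CpG regions), fragment-size effects, spatial
or dye bias, copy-number differences, or cell-type mixture within a tissue.
A green recovery test therefore establishes that the pipeline's interval
logic, scoring and classification recover a clean, well-separated truth — it
does not establish calibration on real arrays, where the raw-peak veto and
probe-coverage gaps make counts conservative in ways the simulation cannot
quantify.

## Numerical notes

* ECDF ties: both ECDFs are right-continuous step functions evaluated at all
  pooled points; `D+` is clamped at 0, so an anti-enriched window yields
  p = 1 and P = 0 rather than a spuriously small two-sided p.
* The P score is capped at 300 (`ks_pvalue_floor = 1e-300`) to stay finite.
* Zero-variance tracks make the Pearson coefficient undefined; the package
  returns `NaN` with a warning rather than guessing.
* `merge_peaks()` is a single sorted sweep that is idempotent and equals a
  per-base dilation oracle; merging is annotation-blind (it may cross
  promoter/CpGi boundaries), because peaks are defined before categories.
* Degenerate inputs: empty region sets flow through every operation as
  zero-row tibbles; a sample with fewer than two replicates aborts the
  pipeline (consensus is defined in terms of two); adult-only designs skip
  the DS-DMR stages with a warning.
* Determinism: all generator randomness derives from one seed (offsets
  +10000/+20000 separate the annotation, truth and track draws, keeping
  every derived seed far below 2³¹); identical configuration and seed
  reproduce byte-identical pipeline outputs, which the test suite checks.

## Worked example

```{r example, eval = FALSE}
experiment <- simulate_experiment(sim_config(seed = 1))
result <- run_medip_pipeline(
  experiment$signal,
  experiment$annotation$probes,
  experiment$annotation$genes,
  experiment$annotation$cpgis,
  medip_config(max_probe_gap_bp = 750),
  tiling_regions = experiment$annotation$tiling_regions
)
glance(result)
result$tdmr$table
glance(result$dsdmr$overlap)
```

On seed 1 this calls 1,554 raw peaks and 769 consensus peaks over 5,479
probes, yielding 139 clean T-DMR records and 91 DS-DMR records, with mean
replicate concordance 0.94 on log2 ratios and 0.98 on P scores — the P-score
concordance exceeding the ratio concordance because windowing removes
sporadic single-probe noise.

## Known limitations

* Location categories depend entirely on the supplied annotation; there is
  no de novo CpG-island detection and no liftover.
* The four priority categories are not exhaustive off-array; we always emit
  a fall-through category (or `NA` in strict mode) rather than dropping
  regions silently.
* The cross-tissue unique fraction is expected to drop as more tissues are
  added; it is an accounting of the sampled design, not a biological
  constant.
* Recovery metrics use 50% reciprocal overlap; boundary bleed of roughly one
  probe per side is normal and occasionally splits off small flagged edge
  atoms, which is the main source of the few percent of false-positive
  records seen in the synthetic benchmark.
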