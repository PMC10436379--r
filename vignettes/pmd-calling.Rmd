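---
title: "Methods: PMD calling, core-domain designation, and rare-read hypomethylation detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMD calling, core-domain designation, and rare-read hypomethylation detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmdscape)
```

## The model

A methylome is observed as sparse per-cell CpG calls: at each covered site
a cell reports `meth`/`total` counts (binary for single-cell bisulfite
data). We model each CpG site as carrying a latent methylation probability:
close to 0.8 in normal genomes (per-site means Beta(16, 4), giving the
familiar unimodal window distribution peaking near 80%), and depressed to a
domain-wide state mean in the 0.20–0.40 range inside partially methylated
domains (PMDs). Preserved methylation islands (PMIs) are sub-intervals of
PMDs that revert to background.

All domain calling happens at the level of a **window track**: pooled
calls of one *source* (a patient's CTCs, a cell line's cells) averaged
over 100-kb windows placed every 200 bp. Windows intersecting CpG islands
or assembly gaps are discarded — CGIs follow promoter-specific dynamics
that would contaminate domain-scale averages — and windows with fewer than
10 covered CpGs are treated as missing. Windows that would extend past a
chromosome end are dropped rather than truncated, so every scored window
has identical width.

## Thresholding: reading the valley

Tumor sources are bimodal in window methylation; normal sources are
unimodal. The hypomethylation threshold is per source:

* estimate the density of scored window methylation with a Gaussian kernel,
  bandwidth 0.03, on a 1,001-point grid over [0, 1];
* modes are local maxima with topographic prominence at least 5% of the
  density maximum;
* the source is *bimodal* if at least two qualifying modes are separated by
  0.20 or more; the threshold is then the grid argmin strictly between the
  two tallest modes (ties broken toward lower methylation);
* otherwise the source is *unimodal* and the threshold is the fixed
  fallback 0.60.

The bandwidth, grid size, prominence and separation constants are our
choices — a deterministic stand-in for reading a histogram valley by eye —
and all live in `pmd_config()`. A minimum of 500 scored windows is required
before a threshold is estimated; below that the estimate would be
dominated by kernel artifacts and the function errors instead.

One numerical caveat worth knowing: between two well-separated, tight
modes the density floor is nearly flat, so the argmin's exact position
within the valley varies by tens of milli-units between runs. Any
threshold inside the valley separates the two states; the consequence is
not misclassification but a boundary shift of up to about half a window at
domain edges (see *What recovery tests show* below).

## Segmentation and core designation

Windows strictly below the threshold are hypomethylated. Overlapping or
book-ended hypomethylated windows merge into maximal runs; runs of at
least 250 kb are the per-source PMDs. Per-source PMIs are the gaps between
two consecutive PMDs on a chromosome with length strictly inside
(30 kb, 3 Mb); chromosome ends are not flanked by PMDs and never produce
PMIs. Totals are genomic unions across sources (merged, order-independent).

Core PMDs: for each total PMD we pool each source's calls over the *union*
interval, quantile-normalize sources against each other
(`limma::normalizeQuantiles`, ties averaged), and flag rows whose mean
normalized methylation is below 25%. We compute source methylation over
the union interval rather than each source's own boundaries because the
normalization is defined across all PMDs of all sources at once; intervals
without coverage in some source are excluded from eligibility and
reported. Core PMIs: a total PMI is core when it overlaps (≥ 1 bp) a
per-source PMI in *every* source; we read "overlapped in all sources" as
any-overlap because no reciprocal-overlap fraction is stated anywhere, and
any-overlap is the weakest assumption.

The `hypomethylated_fraction()` summary — percent of scored bp covered by
merged hypomethylated windows, before the 250-kb filter — excludes missing
windows from numerator and denominator both.

## Long-read detection

For reads with genomic coordinates, only calls inside a PMD and outside
CGIs are *eligible*. A read is classifiable with ≥ 30 eligible calls and
hypomethylated when its mean eligible call is below 0.50. The 0.50 cut is
our default: it bisects the gap between PMD-state (0.20–0.40) and normal
(~0.80) methylation; the per-read cut used on the original patient data is
not published, so the value is exposed in `pmd_config()` and reported in
outputs. Sample QC requires lambda spike-in methylation < 1% and at least
300 (metastatic) / 400 (localized) PMD-aligned reads, where "PMD-aligned"
means ≥ 1 eligible call. For healthy donors we apply 300, the weaker of
the two cohort minima, as donors are compared against both cohorts.
The sample signal is 100 × hypomethylated / classifiable reads; cohort
contrasts use the equal-variance two-tailed t-test, and the positivity
threshold is the maximum signal over the reference (healthy) group.

The spike-in precision–recall model scores labelled reads by
1 − mean methylation, sweeps every observed score as a threshold, and
takes the trapezoid area over the swept points, stratified by CpGs per
read. No interpolation between points and no minimum-call filter are
applied: the model's purpose is exactly to show how precision rises from
~5 calls (short-read regime) to ≥ 30 calls (long-read regime) at a 1%
spike fraction.

## Statistics

The expression screen drops genes whose 95th-percentile expression is
below 1 (FPKM-like floor), computes the textbook pooled-variance t
statistic per gene (vectorized; verified against `stats::t.test` in the
test suite), applies Benjamini–Hochberg across tested genes and calls
FDR < 0.1 significant. Zero-variance genes get p = 1 with a message. Gene
set enrichment is the hypergeometric upper tail `P(X ≥ k)` via `phyper`,
with BH across sets reported alongside the raw p-values. Heterogeneity is
summarized two ways: mean pairwise bp-Jaccard of per-cell hypomethylated
interval sets within a group (two empty sets count 1, one empty set 0),
and mean pairwise Pearson correlation over shared non-missing features
with a leave-one-cell-out jackknife standard error. The CNV score is the
length-weighted mean of |c − 2| over bins, so splitting bins or ragged
terminal bins leave it unchanged.

## The synthetic generator, and what passing tests do and do not show

`synth_spec()` fixes the study conditions the tests run under: a 20-Mb
toy genome (two 10-Mb chromosomes), CpGs every ~100 bp (5× denser inside
CGIs, one CGI per 200 kb, ~1 kb wide), per-site background methylation
Beta(16, 4), planted PMD states drawn uniform [0.20, 0.40], 10 cells at
30% site coverage with one Bernoulli call per covered site, ~10-kb reads,
1% spike fraction, 0.5% lambda error. The default tumor spec plants two
3-Mb PMDs (30% of the genome). Two geometric facts shaped those defaults:

* 100-kb windowing blurs every domain edge by up to ~half a window (the
  exact shift depends on where the valley threshold lands), so planted
  domains must be large relative to 50 kb for bp-Jaccard recovery of 0.95
  to be attainable at all — hence few, multi-Mb planted domains, and a
  2-Mb planted PMI in the PMI-recovery spec.
* CGIs are placed in the complement of planted PMDs. This mirrors the
  biology (PMDs are gene-poor and CGI-poor; PMIs gene-rich) and is also a
  requirement of the window-exclusion rule: CGIs scattered uniformly at
  realistic density would excise so many windows inside domains that
  merged runs fragment below the 250-kb filter.

Generators are pure functions of (spec, seed) — identical seeds give
identical outputs — and every generator returns its planted truth so
recovery can be scored without re-deriving it.

What the synthetic data does **not** emulate: realistic sequence content,
chromosome-scale covariates of methylation (replication timing, gene
density gradients), per-read error structure of any particular chemistry,
copy-number-driven coverage bias, or cell-to-cell biological
heterogeneity beyond Bernoulli sampling (a per-call beta-binomial was
considered and rejected for simplicity: with binary single-cell calls the
two are nearly indistinguishable). Passing recovery tests therefore show
that the implementation performs the stated computation correctly and
recovers structure under its own assumptions — not that the thresholds
would perform identically on real methylomes, where boundary sharpness,
CGI placement and coverage are all less kind.

## Degenerate inputs and tie-breaks

* Coordinates: intervals are 0-based half-open (BED-native); point
  positions (CpGs, probes) are 1-based (Bismark-native). A 1-based
  position `p` is inside `[start, end)` iff `start < p <= end`; conversion
  happens only in readers/writers.
* A window with pooled total of 0 (or < 10 CpGs) is missing, never 0/0.
* Reads with no eligible calls have undefined mean methylation and count 0;
  they fail the classifiability filter rather than erroring.
* A sample with no lambda reads cannot demonstrate lambda QC and fails QC.
* `union_domains` of an empty input errors (no sources) but empty interval
  *sets* propagate as empty tibbles.
* Interval Jaccard of two empty sets is 1, of one empty set 0.
* Valley ties break toward lower methylation; bins exactly at the 50%
  array cut count as unmethylated; the 30-kb/3-Mb PMI bounds and the
  "< 25%" core cutoff are strict.

## Problem sizes

Tests and the acceptance script run the full pipeline at the 20-Mb genome
/ 10-cell scale (~600k calls, ~60k scored windows per source, 16k
labelled reads in the spike-in model) — large enough that window pooling,
valley reading, segmentation and PR sweeps are exercised end-to-end in a
few tens of seconds. `synth_spec()` accepts arbitrary genome tables if
you want full-scale simulations; the algorithms are linear in calls plus
windows (per-chromosome prefix sums, not per-window scans).
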