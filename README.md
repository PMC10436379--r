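# pmdscape

Partially Methylated Domain (PMD) calling from sparse single-cell bisulfite
data, and detection of rare tumor-derived hypomethylation in long-read
methylation calls from CTC-enriched blood.

## The problem

Cancer genomes lose DNA methylation over megabase-scale, gene-poor,
late-replicating blocks — partially methylated domains. In single
circulating tumor cells (CTCs) and prostate cancer cell lines this
hypomethylation covers 20–40% of the genome, while normal cells stay below
2.5%; nested inside PMDs sit smaller, gene-rich *preserved methylation
islands* (PMIs) that keep normal methylation. Because PMD hypomethylation
is an early, stable, tumor-wide mark, reads falling into known PMDs can be
classified tumor/normal by their methylation alone, which turns long-read
sequencing of leukocyte-depleted blood into a rare-cell cancer detector.

`pmdscape` implements that whole computational arc for R users:

* **Window track** — pooled CpG calls per source binned into 100-kb windows
  placed at 200-bp offsets; windows touching CpG islands or assembly gaps
  are discarded, and windows with fewer than 10 covered CpGs are missing.
* **Valley threshold** — each source's window-methylation density (Gaussian
  kernel, bandwidth 0.03 on a 1,001-point grid) is classified unimodal or
  bimodal; bimodal sources get the density minimum between the two modes as
  their hypomethylation threshold, unimodal sources the fixed 60% fallback.
* **Segmentation** — hypomethylated windows (methylation < threshold) are
  merged; runs ≥ 250 kb are the per-source PMDs; gaps between consecutive
  PMDs with length strictly in (30 kb, 3 Mb) are the per-source PMIs.
* **Total and core sets** — totals are genomic unions across sources. Core
  PMDs have averaged quantile-normalized methylation < 25% across all
  sources; core PMIs overlap a per-source PMI in every source.
* **CNV score** — the length-weighted genome average of |copy number − 2|
  per cell.
* **Array metrics** — beta values binned to 10-kb windows, bins below 70%
  mean normal methylation dropped, and global/locus "fraction of bins
  > 50% methylated" metrics (default locus: *CD1A–IFI16*,
  chr1:158,130,000–158,340,000, hg19).
* **Heterogeneity** — pairwise bp-Jaccard of per-cell hypomethylated
  interval sets, and mean pairwise correlation with leave-one-out jackknife
  standard errors.
* **Expression screen** — domain-resident genes filtered at the
  95th-percentile-≥ 1 expression floor, tested by equal-variance two-tailed
  t-test with Benjamini–Hochberg FDR < 0.1, plus hypergeometric gene-set
  enrichment (`phyper` upper tail).
* **Long-read detector** — per-read mean methylation over calls inside PMDs
  and outside CpG islands; reads need ≥ 30 eligible calls; sample QC needs
  lambda spike-in methylation < 1% and ≥ 300 (metastatic) / 400 (localized)
  PMD-aligned reads; the sample signal is the percent of passing reads that
  are hypomethylated; plus an in-silico 1%-spike-in precision–recall model.
* **Synthetic data** — generators for every input above (methylomes with
  planted PMDs/PMIs, labelled long reads, copy-number profiles, beta and
  expression matrices), so the full pipeline runs and is tested without any
  external download.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a tumor methylome on the 20-Mb toy genome (two 3-Mb PMDs planted,
30% of the genome), then run the calling pipeline:

```r
library(pmdscape)

sim   <- generate_methylome(synth_tumor_spec(seed = 42))
track <- build_window_track(sim$calls, sim$layout)
thr   <- select_threshold(track)
tidy(thr)
#> # A tibble: 1 × 6
#>   source modality threshold mode_lo mode_hi n_windows
#>   <chr>  <chr>        <dbl>   <dbl>   <dbl>     <int>
#> 1 tumor1 bimodal      0.676   0.304     0.8     62530

call_pmds_per_source(track, thr)
#> # A tibble: 2 × 5
#>   source kind  chrom   start     end
#>   <chr>  <chr> <chr>   <dbl>   <dbl>
#> 1 tumor1 PMD   chr1   922600 4082400
#> 2 tumor1 PMD   chr2  1933000 5076400

hypomethylated_fraction(track, thr)
#> # A tibble: 1 × 4
#>   source hypo_bp scored_bp percent
#>   <chr>    <dbl>     <dbl>   <dbl>
#> 1 tumor1 6303200  17795400    35.4
```

The source is bimodal, so the threshold (0.676) is the density valley
rather than the 60% fallback. The two called PMDs recover the planted
domains to within about half a window width per edge (bp-Jaccard 0.95
against the planted truth), and 35% of the scored genome is
hypomethylated — inside the 20–40% band expected of tumor methylomes.
`autoplot(thr)` draws the window-methylation density with the threshold;
`write_domains()` saves the calls as BED.

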