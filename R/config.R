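#' Pipeline configuration
#'
#' All tunable parameters of the domain-calling and long-read detection
#' pipeline in one place. Defaults are the published working values of the
#' method: 100-kb windows at 200-bp offsets with at least 10 covered CpGs,
#' a 60% fallback threshold for unimodal sources, a 250-kb minimum PMD
#' length, PMI lengths strictly between 30 kb and 3 Mb, a 25% cutoff on
#' averaged quantile-normalized methylation for core PMDs, at least 30
#' confident CpG calls per long read, per-cohort minima of 300 (metastatic)
#' and 400 (localized) PMD-aligned reads, and a <1% lambda spike-in bound.
#'
#' @param window_size Sliding-window width in bp.
#' @param window_step Offset between consecutive window starts in bp.
#' @param min_cpgs_per_window Minimum covered CpG sites for a window to be
#'   scored; windows below this are reported with missing methylation.
#' @param min_windows Minimum number of scored windows required before a
#'   source threshold is estimated.
#' @param fallback_threshold Hypomethylation threshold used when the window
#'   methylation distribution is unimodal.
#' @param density_n,density_bw Grid size and Gaussian kernel bandwidth for
#'   the window-methylation density on \[0, 1\].
#' @param mode_prominence Minimum topographic prominence of a density mode,
#'   as a fraction of the global density maximum, for it to qualify.
#' @param mode_separation Minimum separation (methylation units) between the
#'   two dominant modes for the distribution to be declared bimodal.
#' @param min_pmd_length Minimum merged hypomethylated run length kept as a
#'   PMD, in bp.
#' @param pmi_min_length,pmi_max_length Exclusive bounds on PMI length, bp.
#' @param core_pmd_cutoff Row-mean quantile-normalized methylation below
#'   which a PMD is designated core.
#' @param min_cpgs_per_read Minimum eligible CpG calls for a long read to be
#'   classified.
#' @param read_hypo_threshold Per-read mean methylation below which a
#'   passing read is called hypomethylated.
#' @param min_reads_metastatic,min_reads_localized,min_reads_healthy
#'   Per-cohort minimum number of PMD-aligned reads for sample QC.
#' @param lambda_max Maximum tolerated methylated fraction on lambda
#'   spike-in calls.
#' @param qc_min_unique_cpgs,qc_min_conversion Cell-level QC: minimum unique
#'   covered CpG sites and minimum bisulfite conversion rate.
#' @param array_bin Array-metric bin width, bp.
#' @param array_normal_floor Bins whose mean methylation over normal samples
#'   falls below this are dropped from array metrics.
#' @param array_hypo_cut Bin methylation above which a bin counts as
#'   methylated in the array fraction metrics (strict inequality).
#' @param de_fdr Benjamini-Hochberg FDR cutoff for the expression screen.
#' @param de_expr_floor_percentile,de_expr_floor Genes whose expression at
#'   this percentile falls below the floor are discarded before testing.
#'
#' @return A list of class `pmd_config`.
#' @export
#' @examples
#' cfg <- pmd_config()
#' cfg$fallback_threshold
pmd_config <- function(window_size = 100000L,
                       window_step = 200L,
                       min_cpgs_per_window = 10L,
                       min_windows = 500L,
                       fallback_threshold = 0.60,
                       density_n = 1001L,
                       density_bw = 0.03,
                       mode_prominence = 0.05,
                       mode_separation = 0.20,
                       min_pmd_length = 250000L,
                       pmi_min_length = 30000L,
                       pmi_max_length = 3000000L,
                       core_pmd_cutoff = 0.25,
                       min_cpgs_per_read = 30L,
                       read_hypo_threshold = 0.50,
                       min_reads_metastatic = 300L,
                       min_reads_localized = 400L,
                       min_reads_healthy = 300L,
                       lambda_max = 0.01,
                       qc_min_unique_cpgs = 4e6,
                       qc_min_conversion = 0.98,
                       array_bin = 10000L,
                       array_normal_floor = 0.70,
                       array_hypo_cut = 0.50,
                       de_fdr = 0.1,
                       de_expr_floor_percentile = 0.95,
                       de_expr_floor = 1) {
  cfg <- as.list(environment())
  lens <- c("window_size", "window_step", "min_pmd_length", "pmi_min_length",
            "pmi_max_length", "array_bin")
  for (nm in lens) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("`", nm, "` must be a positive length in bp", call. = FALSE)
    }
  }
  fr <- c("fallback_threshold", "core_pmd_cutoff", "read_hypo_threshold",
          "lambda_max", "qc_min_conversion", "array_normal_floor",
          "array_hypo_cut", "de_fdr", "de_expr_floor_percentile")
  for (nm in fr) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$window_step > cfg$window_size) {
    stop("`window_step` must not exceed `window_size`", call. = FALSE)
  }
  if (cfg$pmi_min_length >= cfg$pmi_max_length) {
    stop("`pmi_min_length` must be below `pmi_max_length`", call. = FALSE)
  }
  structure(cfg, class = "pmd_config")
}

#' @export
print.pmd_config <- function(x, ...) {
  cat("<pmd_config>\n")
  cat(sprintf("  windows: %d bp @ %d bp offsets, >= %d CpGs\n",
              x$window_size, x$window_step, x$min_cpgs_per_window))
  cat(sprintf("  threshold: valley (bw %.3f) | fallback %.2f\n",
              x$density_bw, x$fallback_threshold))
  cat(sprintf("  PMD >= %s bp; PMI in (%s, %s) bp; core < %.0f%%\n",
              format(x$min_pmd_length, big.mark = ","),
              format(x$pmi_min_length, big.mark = ","),
              format(x$pmi_max_length, big.mark = ","),
              100 * x$core_pmd_cutoff))
  cat(sprintf("  long reads: >= %d CpGs, hypo < %.2f, lambda < %.2f%%\n",
              x$min_cpgs_per_read, x$read_hypo_threshold, 100 * x$lambda_max))
  invisible(x)
}

# Reference interval of the array locus metric (hg19): the CD1A-IFI16
# gene cluster on chromosome 1.
#' CD1A-IFI16 locus (hg19)
#'
#' The default interval of [locus_methylation()]: the lipid-antigen
#' presentation / interferon-inducible gene cluster on chromosome 1
#' whose hypomethylation tracks prostate-cancer progression.
#'
#' @format A tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
cd1a_ifi16_locus <- function() {
  tibble::tibble(chrom = "chr1", start = 158130000L, end = 158340000L)
}
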