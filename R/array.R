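#' Bin a beta-value probe matrix into fixed genomic windows
#'
#' Probes are assigned to non-overlapping `cfg$array_bin`-bp bins
#' (bin k = \[k*bin, (k+1)*bin)) by position; each bin value is the mean
#' beta of its probes per sample (missing betas ignored). Bins without
#' probes are absent from the output.
#'
#' @param beta Probes x samples numeric matrix (rownames = probe ids).
#' @param probes Tibble `probe`, `chrom`, `pos` (1-based) matching the
#'   matrix rows.
#' @param cfg A [pmd_config()].
#'
#' @return A tibble `chrom`, `start`, `end` plus one column per sample.
#' @export
bin_beta_matrix <- function(beta, probes, cfg = pmd_config()) {
  stopifnot(is.matrix(beta), nrow(beta) == nrow(probes))
  bin <- cfg$array_bin
  key <- tibble::tibble(chrom = probes$chrom,
                        start = floor((probes$pos - 1) / bin) * bin)
  d <- dplyr::bind_cols(key, tibble::as_tibble(beta))
  out <- d |>
    dplyr::group_by(.data$chrom, .data$start) |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    dplyr::mutate(end = .data$start + bin, .after = "start") |>
    dplyr::arrange(.data$chrom, .data$start)
  out[] <- lapply(out, function(x) replace(x, is.nan(x), NA_real_))
  out
}

#' Drop bins methylated below a floor in normal samples
#'
#' Removes bins whose methylation, averaged across all normal samples,
#' is below `cfg$array_normal_floor` (70%): the metrics downstream count
#' loss of methylation, so only bins methylated in normal tissue are
#' informative.
#'
#' @param binned Binned tibble from [bin_beta_matrix()].
#' @param groups Named vector mapping sample column names to
#'   `"tumor"`/`"normal"`.
#' @param cfg A [pmd_config()].
#'
#' @return The filtered binned tibble.
#' @export
filter_bins_by_normal <- function(binned, groups, cfg = pmd_config()) {
  normals <- names(groups)[groups == "normal"]
  if (length(normals) == 0) stop("no normal samples in `groups`", call. = FALSE)
  stopifnot(all(normals %in% names(binned)))
  nm <- rowMeans(as.matrix(binned[, normals, drop = FALSE]), na.rm = TRUE)
  binned[!is.na(nm) & nm >= cfg$array_normal_floor, , drop = FALSE]
}

#' Array methylation metrics: global and locus bin fractions
#'
#' The global metric is the fraction of retained bins with methylation
#' strictly above `cfg$array_hypo_cut` (50%) in the given sample; the
#' locus metric is the same fraction restricted to bins overlapping an
#' interval (default: the CD1A-IFI16 locus, [cd1a_ifi16_locus()]).
#'
#' @param binned Filtered binned tibble (see [filter_bins_by_normal()]).
#' @param sample Sample column name.
#' @param cfg A [pmd_config()].
#' @return A fraction in \[0, 1\], or `NA` when no retained bin qualifies.
#' @export
global_methylation <- function(binned, sample, cfg = pmd_config()) {
  stopifnot(sample %in% names(binned))
  v <- binned[[sample]]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v > cfg$array_hypo_cut)
}

#' @rdname global_methylation
#' @param interval One-row tibble `chrom`, `start`, `end`.
#' @export
locus_methylation <- function(binned, sample, interval = cd1a_ifi16_locus(),
                              cfg = pmd_config()) {
  hit <- overlaps_any(binned[, c("chrom", "start", "end")],
                      tibble::as_tibble(interval))
  sub <- binned[hit, , drop = FALSE]
  if (nrow(sub) == 0) {
    message("no retained bins overlap the locus; returning NA")
    return(NA_real_)
  }
  global_methylation(sub, sample, cfg)
}
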