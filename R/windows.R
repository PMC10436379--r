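#' Build per-source sliding-window methylation tracks
#'
#' Bins pooled CpG calls into `window_size`-bp windows placed at
#' `window_step`-bp offsets (defaults 100 kb / 200 bp). Windows that would
#' extend past a chromosome end are dropped, as are windows intersecting
#' any CpG island or assembly gap. Window methylation is the pooled
#' (sum methylated) / (sum total) over all cells of the source for CpG
#' sites inside the window, and is missing when fewer than
#' `min_cpgs_per_window` distinct sites are covered.
#'
#' Window sums are computed from per-chromosome cumulative sums over the
#' sorted pooled sites, so cost is linear in sites plus windows rather
#' than sites times windows.
#'
#' @param calls Call tibble (`cell`, `source`, `chrom`, `pos`, `meth`,
#'   `total`), e.g. from [read_cpg_calls()] or [generate_methylome()].
#' @param layout A [genome_layout()].
#' @param cfg A [pmd_config()].
#'
#' @return A tibble `source`, `chrom`, `start`, `end` (0-based half-open),
#'   `meth` (fraction or `NA`), `n_cpg` (covered sites).
#' @export
#' @examples
#' sim <- generate_methylome(synth_normal_spec(seed = 1))
#' track <- build_window_track(sim$calls, sim$layout)
build_window_track <- function(calls, layout, cfg = pmd_config()) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0 || length(unique(calls$source)) == 0) {
    stop("no sources present in `calls`", call. = FALSE)
  }
  W <- cfg$window_size
  step <- cfg$window_step
  excl <- dplyr::bind_rows(layout$cgi, layout$gaps)

  # pooled per-site counts per (source, chrom)
  pooled <- calls |>
    dplyr::group_by(.data$source, .data$chrom, .data$pos) |>
    dplyr::summarise(meth = sum(.data$meth), total = sum(.data$total),
                     .groups = "drop")

  out <- list()
  for (src in unique(pooled$source)) {
    for (i in seq_len(nrow(layout$chromosomes))) {
      ch <- layout$chromosomes$chrom[i]
      L <- layout$chromosomes$length[i]
      if (L < W) next
      starts <- seq(0, L - W, by = step)
      keep <- rep(TRUE, length(starts))
      ex <- excl[excl$chrom == ch, ]
      if (nrow(ex) > 0) {
        keep <- !IRanges::overlapsAny(
          IRanges::IRanges(starts + 1, starts + W),
          IRanges::IRanges(ex$start + 1, ex$end)
        )
      }
      starts <- starts[keep]
      if (length(starts) == 0) next
      s <- pooled[pooled$source == src & pooled$chrom == ch, ]
      s <- s[order(s$pos), ]
      csm <- c(0, cumsum(s$meth))
      cst <- c(0, cumsum(s$total))
      hi <- findInterval(starts + W, s$pos) + 1
      lo <- findInterval(starts, s$pos) + 1
      n_cpg <- hi - lo
      tot <- cst[hi] - cst[lo]
      meth <- ifelse(n_cpg >= cfg$min_cpgs_per_window & tot > 0,
                     (csm[hi] - csm[lo]) / tot, NA_real_)
      out[[length(out) + 1]] <- tibble::tibble(
        source = src, chrom = ch, start = starts, end = starts + W,
        meth = meth, n_cpg = n_cpg
      )
    }
  }
  dplyr::bind_rows(out)
}
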