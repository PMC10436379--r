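#' Call per-source PMDs
#'
#' Windows with methylation strictly below the source threshold are marked
#' hypomethylated; overlapping or book-ended hypomethylated windows are
#' merged into maximal runs (span = min start to max end), and runs
#' shorter than `cfg$min_pmd_length` (250 kb) are removed.
#'
#' @param track Window track from [build_window_track()].
#' @param thr A `pmd_threshold` tibble from [select_threshold()].
#' @param cfg A [pmd_config()].
#'
#' @return A tibble `source`, `chrom`, `start`, `end`, `kind = "PMD"`,
#'   sorted and non-overlapping within each source.
#' @export
call_pmds_per_source <- function(track, thr, cfg = pmd_config()) {
  stopifnot(all(thr$threshold >= 0 & thr$threshold <= 1))
  out <- lapply(seq_len(nrow(thr)), function(i) {
    src <- thr$source[i]
    t <- thr$threshold[i]
    w <- track[track$source == src & !is.na(track$meth) & track$meth < t, ]
    if (nrow(w) == 0) return(NULL)
    m <- merge_intervals(w[, c("chrom", "start", "end")])
    m <- m[m$end - m$start >= cfg$min_pmd_length, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    dplyr::mutate(m, source = src, kind = "PMD", .before = 1)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(source = character(), kind = character(),
                          chrom = character(), start = double(), end = double())
  }
  res
}

#' Merge per-source domain sets into a total set
#'
#' The genomic union: overlapping or book-ended intervals from any source
#' are merged. Idempotent, commutative and associative.
#'
#' @param domains A tibble of intervals (any number of sources; extra
#'   columns ignored), or a list of such tibbles.
#' @param kind Label for the output `kind` column (default taken from the
#'   input when unambiguous).
#'
#' @return A tibble `chrom`, `start`, `end`, `kind`, sorted and
#'   non-overlapping.
#' @export
#' @examples
#' union_domains(data.frame(chrom = "chr1",
#'                          start = c(0, 5e5), end = c(1e6, 1.5e6)))
union_domains <- function(domains, kind = NULL) {
  if (is.data.frame(domains)) domains <- list(domains)
  if (length(domains) == 0) stop("at least one source required", call. = FALSE)
  all <- dplyr::bind_rows(lapply(domains, tibble::as_tibble))
  if (is.null(kind)) {
    kind <- if ("kind" %in% names(all) && length(unique(all$kind)) == 1) {
      unique(all$kind)
    } else "domain"
  }
  if (nrow(all) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), kind = character()))
  }
  dplyr::mutate(merge_intervals(all), kind = kind)
}

#' Call per-source PMIs
#'
#' A preserved methylation island is a gap between two consecutive PMDs of
#' the same source on the same chromosome whose length is strictly between
#' `cfg$pmi_min_length` (30 kb) and `cfg$pmi_max_length` (3 Mb).
#' Chromosome ends are not flanked by PMDs and never yield PMIs.
#'
#' @param pmds Per-source PMD tibble from [call_pmds_per_source()].
#' @param cfg A [pmd_config()].
#'
#' @return A tibble `source`, `chrom`, `start`, `end`, `kind = "PMI"`.
#' @export
call_pmis_per_source <- function(pmds, cfg = pmd_config()) {
  if (!"source" %in% names(pmds)) pmds$source <- "source1"
  out <- pmds |>
    dplyr::group_by(.data$source, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(gap_start = head(.data$end, -1),
                   gap_end = tail(.data$start, -1)) |>
    dplyr::rename(start = "gap_start", end = "gap_end") |>
    dplyr::filter(.data$end - .data$start > cfg$pmi_min_length,
                  .data$end - .data$start < cfg$pmi_max_length) |>
    dplyr::mutate(kind = "PMI")
  out[, c("source", "chrom", "start", "end", "kind")]
}

# Pooled methylation of each source within each interval.
domain_source_methylation <- function(intervals, calls) {
  sources <- unique(calls$source)
  M <- matrix(NA_real_, nrow(intervals), length(sources),
              dimnames = list(NULL, sources))
  pooled <- calls |>
    dplyr::group_by(.data$source, .data$chrom, .data$pos) |>
    dplyr::summarise(meth = sum(.data$meth), total = sum(.data$total),
                     .groups = "drop")
  for (src in sources) {
    for (ch in unique(intervals$chrom)) {
      ii <- which(intervals$chrom == ch)
      s <- pooled[pooled$source == src & pooled$chrom == ch, ]
      if (nrow(s) == 0) next
      s <- s[order(s$pos), ]
      csm <- c(0, cumsum(s$meth))
      cst <- c(0, cumsum(s$total))
      hi <- findInterval(intervals$end[ii], s$pos) + 1
      lo <- findInterval(intervals$start[ii], s$pos) + 1
      tot <- cst[hi] - cst[lo]
      M[ii, src] <- ifelse(tot > 0, (csm[hi] - csm[lo]) / tot, NA_real_)
    }
  }
  M
}

#' Designate core PMDs by quantile-normalized methylation
#'
#' For every total (union) PMD interval, the pooled methylation of each
#' source over that interval is computed; sources are then quantile
#' normalized against one another (rank to mean of order statistics, ties
#' averaged) and a PMD is core when its row mean of normalized values is
#' below `cfg$core_pmd_cutoff` (25%). Intervals lacking CpG coverage in
#' any source are excluded from core eligibility and reported.
#'
#' @param total Total PMD tibble from [union_domains()].
#' @param calls Multi-source call tibble.
#' @param cfg A [pmd_config()].
#'
#' @return An object of class `pmd_core`: list with `domains` (the total
#'   intervals plus `qn_mean` and `core`), `meth` (raw per-source matrix),
#'   `qn` (quantile-normalized matrix), `cutoff`.
#' @export
designate_core_pmds <- function(total, calls, cfg = pmd_config()) {
  total <- tibble::as_tibble(total)
  M <- domain_source_methylation(total, calls)
  res <- core_from_matrix(M, cutoff = cfg$core_pmd_cutoff)
  n_drop <- sum(!res$eligible)
  if (n_drop > 0) {
    message(n_drop, " PMD(s) uncovered in at least one source; ",
            "excluded from core eligibility")
  }
  domains <- dplyr::mutate(total[, c("chrom", "start", "end")],
                           kind = "PMD", qn_mean = res$qn_mean,
                           core = res$core)
  structure(list(domains = domains, meth = M, qn = res$qn,
                 cutoff = cfg$core_pmd_cutoff),
            class = "pmd_core")
}

#' Core designation from a per-domain source methylation matrix
#'
#' The quantile-normalization and cutoff step of [designate_core_pmds()],
#' usable directly on a constructed domains x sources matrix.
#'
#' @param M Numeric matrix, domains x sources, methylation fractions.
#' @param cutoff Row-mean cutoff on normalized values.
#' @return A list: `qn` (normalized matrix), `qn_mean` (row means),
#'   `core` (logical), `eligible` (rows with complete data).
#' @export
core_from_matrix <- function(M, cutoff = 0.25) {
  stopifnot(is.matrix(M), ncol(M) >= 1)
  eligible <- complete.cases(M)
  qn <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  if (sum(eligible) > 0) {
    qn[eligible, ] <- limma::normalizeQuantiles(M[eligible, , drop = FALSE],
                                                ties = TRUE)
  }
  qn_mean <- rowMeans(qn)
  core <- eligible & !is.na(qn_mean) & qn_mean < cutoff
  list(qn = qn, qn_mean = qn_mean, core = core, eligible = eligible)
}

#' @export
print.pmd_core <- function(x, ...) {
  cat(sprintf("<pmd_core> %d domains x %d sources; %d core (< %.0f%%)\n",
              nrow(x$domains), ncol(x$meth), sum(x$domains$core),
              100 * x$cutoff))
  invisible(x)
}

#' @rdname designate_core_pmds
#' @param x,object A `pmd_core` object.
#' @param ... Unused.
#' @export
tidy.pmd_core <- function(x, ...) {
  d <- x$domains
  long <- dplyr::bind_rows(lapply(colnames(x$meth), function(src) {
    tibble::tibble(chrom = d$chrom, start = d$start, end = d$end,
                   source = src, meth = x$meth[, src], qn_meth = x$qn[, src])
  }))
  dplyr::left_join(long, d[, c("chrom", "start", "end", "qn_mean", "core")],
                   by = c("chrom", "start", "end"))
}

#' @rdname designate_core_pmds
#' @export
glance.pmd_core <- function(x, ...) {
  tibble::tibble(n_domains = nrow(x$domains), n_sources = ncol(x$meth),
                 n_core = sum(x$domains$core), cutoff = x$cutoff)
}

#' Designate core PMIs by cross-source overlap
#'
#' Total PMIs are the union of per-source PMIs; a union interval is core
#' when it overlaps (by at least 1 bp) a per-source PMI in every source.
#'
#' @param pmis Per-source PMI tibble from [call_pmis_per_source()].
#' @param sources Optional character vector of all sources that must be
#'   matched (defaults to those present in `pmis`).
#'
#' @return A tibble `chrom`, `start`, `end`, `kind = "PMI"`, `core`.
#' @export
designate_core_pmis <- function(pmis, sources = NULL) {
  stopifnot("source" %in% names(pmis))
  sources <- sources %||% unique(pmis$source)
  if (length(sources) == 0) stop("at least one source required", call. = FALSE)
  total <- union_domains(pmis, kind = "PMI")
  if (nrow(total) == 0) return(dplyr::mutate(total, core = logical(0)))
  hit <- vapply(sources, function(src) {
    overlaps_any(total, pmis[pmis$source == src, ])
  }, logical(nrow(total)))
  if (nrow(total) == 1) hit <- matrix(hit, nrow = 1)
  dplyr::mutate(total, core = rowSums(hit) == length(sources))
}

#' Hypomethylated fraction of the scored genome
#'
#' 100 x (bp covered by merged hypomethylated windows, before the minimum
#' PMD length filter) / (bp covered by all scored windows). Windows with
#' missing methylation are excluded from numerator and denominator.
#'
#' @param track Window track from [build_window_track()].
#' @param thr A `pmd_threshold` tibble from [select_threshold()].
#'
#' @return A tibble `source`, `hypo_bp`, `scored_bp`, `percent`.
#' @export
hypomethylated_fraction <- function(track, thr) {
  stopifnot(all(thr$threshold >= 0 & thr$threshold <= 1))
  rows <- lapply(seq_len(nrow(thr)), function(i) {
    src <- thr$source[i]
    w <- track[track$source == src & !is.na(track$meth), ]
    scored_bp <- if (nrow(w)) interval_bp(w[, c("chrom", "start", "end")]) else 0
    h <- w[w$meth < thr$threshold[i], ]
    hypo_bp <- if (nrow(h)) interval_bp(h[, c("chrom", "start", "end")]) else 0
    tibble::tibble(source = src, hypo_bp = hypo_bp, scored_bp = scored_bp,
                   percent = ifelse(scored_bp > 0, 100 * hypo_bp / scored_bp,
                                    NA_real_))
  })
  dplyr::bind_rows(rows)
}

#' bp-level Jaccard index between two interval sets
#'
#' Overlap bp / union bp after merging each set. Two empty sets have
#' Jaccard 1; one empty set gives 0.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' interval_jaccard(data.frame(chrom = "c", start = 0, end = 100),
#'                  data.frame(chrom = "c", start = 50, end = 150))
interval_jaccard <- function(a, b) {
  a_bp <- interval_bp(a); b_bp <- interval_bp(b)
  if (a_bp == 0 && b_bp == 0) return(1)
  ov <- interval_bp(intersect_intervals(a, b))
  un <- interval_bp(merge_intervals(dplyr::bind_rows(
    tibble::as_tibble(a)[, c("chrom", "start", "end")],
    tibble::as_tibble(b)[, c("chrom", "start", "end")]
  )))
  ov / un
}
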