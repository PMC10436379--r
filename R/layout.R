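#' Genome layout
#'
#' Chromosome sizes plus the interval annotations the window scorer must
#' avoid: CpG islands and assembly gaps. Intervals are 0-based half-open
#' (BED convention); point coordinates elsewhere in the package (CpG and
#' probe positions) are 1-based.
#'
#' @param chromosomes Data frame with columns `chrom` and `length` (bp).
#'   Row order fixes the chromosome order used by all writers.
#' @param cgi,gaps Optional data frames of intervals (`chrom`, `start`,
#'   `end`) for CpG islands and assembly gaps; normalized (sorted, merged)
#'   on construction.
#'
#' @return An object of class `genome_layout`: a list with tibbles
#'   `chromosomes`, `cgi`, `gaps`.
#' @export
#' @examples
#' genome_layout(data.frame(chrom = "chr1", length = 1e6))
genome_layout <- function(chromosomes, cgi = NULL, gaps = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom)) {
    stop("duplicated chromosome names in layout", call. = FALSE)
  }
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  chromosomes$length <- as.double(chromosomes$length)
  empty <- tibble::tibble(chrom = character(), start = double(), end = double())
  norm <- function(x) {
    if (is.null(x) || nrow(tibble::as_tibble(x)) == 0) return(empty)
    x <- check_intervals(x, chromosomes)
    merge_intervals(x)
  }
  structure(
    list(chromosomes = chromosomes, cgi = norm(cgi), gaps = norm(gaps)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosomes, %s bp; %d CGIs, %d gaps\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              nrow(x$cgi), nrow(x$gaps)))
  invisible(x)
}

check_intervals <- function(x, chromosomes) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x$start <- as.double(x$start)
  x$end <- as.double(x$end)
  if (any(x$end <= x$start)) {
    stop("intervals must have end > start", call. = FALSE)
  }
  lens <- setNames(chromosomes$length, chromosomes$chrom)
  bad <- !(x$chrom %in% names(lens)) | x$start < 0 | x$end > lens[x$chrom]
  if (any(bad)) {
    stop(sum(bad), " interval(s) outside declared chromosomes", call. = FALSE)
  }
  x
}

# Sort + merge overlapping and book-ended intervals; extra columns dropped.
merge_intervals <- function(x) {
  x <- tibble::as_tibble(x)[, c("chrom", "start", "end")]
  if (nrow(x) == 0) return(x)
  out <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    tibble::tibble(chrom = d$chrom[1],
                   start = as.double(IRanges::start(ir) - 1),
                   end = as.double(IRanges::end(ir)))
  })
  sort_intervals(dplyr::bind_rows(out))
}

sort_intervals <- function(x, chrom_order = NULL) {
  if (is.null(chrom_order)) chrom_order <- unique(sort(x$chrom))
  x$chrom <- as.character(x$chrom)
  x[order(match(x$chrom, chrom_order), x$start, x$end), , drop = FALSE]
}

# Total bp covered by a (possibly unmerged) interval set.
interval_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Intersection of two interval sets, returned merged.
intersect_intervals <- function(x, y) {
  x <- merge_intervals(x); y <- merge_intervals(y)
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  common <- intersect(unique(x$chrom), unique(y$chrom))
  out <- lapply(common, function(ch) {
    a <- x[x$chrom == ch, ]; b <- y[y$chrom == ch, ]
    ir <- IRanges::intersect(
      IRanges::IRanges(a$start + 1, a$end),
      IRanges::IRanges(b$start + 1, b$end)
    )
    if (length(ir) == 0) return(NULL)
    tibble::tibble(chrom = ch, start = as.double(IRanges::start(ir) - 1),
                   end = as.double(IRanges::end(ir)))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  sort_intervals(res)
}

# For each row of `query` (chrom/start/end), TRUE if it overlaps >= 1 bp of
# `subject`.
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (is.null(subject) || nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  hit <- rep(FALSE, nrow(query))
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    s <- subject[subject$chrom == ch, ]
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(query$start[qi] + 1, query$end[qi]),
      IRanges::IRanges(s$start + 1, s$end)
    )
    hit[qi] <- ov
  }
  hit
}

# Membership of 1-based point positions in a 0-based half-open interval set:
# position p is inside [start, end) iff start < p <= end.
positions_in_intervals <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  inside <- rep(FALSE, length(pos))
  if (is.null(intervals) || nrow(intervals) == 0) return(inside)
  for (ch in intersect(unique(chrom), unique(intervals$chrom))) {
    qi <- which(chrom == ch)
    s <- intervals[intervals$chrom == ch, ]
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(pos[qi], pos[qi]),
      IRanges::IRanges(s$start + 1, s$end)
    )
    inside[qi] <- ov
  }
  inside
}
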