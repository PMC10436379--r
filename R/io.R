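#' Read per-CpG methylation calls
#'
#' Parses Bismark coverage files (`chrom pos pos pct n_meth n_unmeth`,
#' 1-based inclusive positions) or bedGraph-style files (0-based half-open;
#' either 6 columns with counts in columns 5-6, or 4 columns of binary
#' percentages for single-call data). Counts are preserved exactly; the
#' 0-based bedGraph start is converted to the 1-based CpG position at parse
#' time, so downstream code sees one uniform convention.
#'
#' @param path File path.
#' @param format `"bismark-cov"` or `"bedgraph"`.
#' @param cell,source Labels attached to every record (one file = one cell).
#'
#' @return A tibble with columns `cell`, `source`, `chrom`, `pos` (1-based),
#'   `meth`, `total`.
#' @export
read_cpg_calls <- function(path, format = c("bismark-cov", "bedgraph"),
                           cell = basename(path), source = cell) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  empty <- tibble::tibble(cell = character(), source = character(),
                          chrom = character(), pos = double(),
                          meth = double(), total = double())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (format == "bismark-cov") {
    bad <- which(nf != 6)
    if (length(bad)) {
      stop("malformed bismark-cov line ", bad[1], " in ", path, call. = FALSE)
    }
    m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
    pos <- as.double(m[, 2])
    meth <- as.double(m[, 5])
    total <- meth + as.double(m[, 6])
  } else {
    if (all(nf == 6)) {
      m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
      pos <- as.double(m[, 2]) + 1  # 0-based half-open start -> 1-based site
      meth <- as.double(m[, 5])
      total <- meth + as.double(m[, 6])
    } else if (all(nf == 4)) {
      m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
      pos <- as.double(m[, 2]) + 1
      pct <- as.double(m[, 4])
      if (any(!pct %in% c(0, 100))) {
        stop("4-column bedGraph without counts must be binary (0/100); ",
             "line ", which(!pct %in% c(0, 100))[1], call. = FALSE)
      }
      meth <- pct / 100
      total <- rep(1, nrow(m))
    } else {
      stop("malformed bedGraph line ", which(nf != nf[1])[1], " in ", path,
           call. = FALSE)
    }
  }
  if (anyNA(pos) || anyNA(meth) || anyNA(total)) {
    stop("non-numeric field in ", path, call. = FALSE)
  }
  if (any(meth > total)) {
    stop("methylated count exceeds total on line ",
         which(meth > total)[1], " of ", path, call. = FALSE)
  }
  tibble::tibble(cell = cell, source = source,
                 chrom = m[, 1], pos = pos, meth = meth, total = total)
}

#' Write per-CpG methylation calls (Bismark coverage dialect)
#'
#' @param calls Tibble as returned by [read_cpg_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  pct <- ifelse(calls$total > 0, 100 * calls$meth / calls$total, 0)
  out <- data.frame(calls$chrom, format(calls$pos, scientific = FALSE, trim = TRUE),
                    format(calls$pos, scientific = FALSE, trim = TRUE),
                    pct, calls$meth, calls$total - calls$meth)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read per-read long-read methylation calls
#'
#' Expects a tab-separated file with columns `read_id`, `chrom`, `pos`
#' (1-based CpG position), `call` (0/1), with or without a header line.
#' Calls are grouped by read and sorted by position; reads on a lambda
#' spike-in contig are flagged. Records on contigs absent from `layout`
#' (when given) are skipped with a warning that reports the count.
#'
#' @param path File path.
#' @param sample Sample label attached to every read.
#' @param lambda_contigs Contig names treated as lambda spike-in.
#' @param layout Optional [genome_layout()] used to screen contigs.
#'
#' @return A tibble of reads with columns `read_id`, `sample`, `chrom`,
#'   `start`, `end` (0-based half-open span of the calls), `is_lambda`,
#'   and a `calls` list-column of tibbles (`pos`, `call`).
#' @export
read_longread_calls <- function(path, sample = basename(path),
                                lambda_contigs = c("lambda", "chrL", "J02459.1"),
                                layout = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  # tolerate a header row (non-numeric position field)
  if (length(lines) > 0) {
    f1 <- strsplit(lines[1], "\t")[[1]]
    if (length(f1) >= 3 && is.na(suppressWarnings(as.double(f1[3])))) {
      lines <- lines[-1]
    }
  }
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 4)) {
    stop("malformed long-read call line ", which(lengths(f) < 4)[1], " in ",
         path, call. = FALSE)
  }
  d <- tibble::tibble(
    read_id = vapply(f, `[`, "", 1),
    chrom = vapply(f, `[`, "", 2),
    pos = as.double(vapply(f, `[`, "", 3)),
    call = as.double(vapply(f, `[`, "", 4))
  )
  if (anyNA(d$pos) || anyNA(d$call)) {
    stop("malformed long-read call file: ", path, call. = FALSE)
  }
  if (!is.null(layout)) {
    known <- c(layout$chromosomes$chrom, lambda_contigs)
    drop <- !(d$chrom %in% known)
    if (any(drop)) {
      warning(sum(drop), " call(s) on unknown contigs skipped in ", path,
              call. = FALSE)
      d <- d[!drop, , drop = FALSE]
    }
  }
  longreads_from_calls(d, sample = sample, lambda_contigs = lambda_contigs)
}

# Build the read-level tibble from a long table of calls.
longreads_from_calls <- function(d, sample, lambda_contigs = "lambda") {
  if (nrow(d) == 0) {
    return(tibble::tibble(read_id = character(), sample = character(),
                          chrom = character(), start = double(), end = double(),
                          is_lambda = logical(), calls = list()))
  }
  d <- dplyr::arrange(d, .data$read_id, .data$pos)
  spans <- d |>
    dplyr::group_by(.data$read_id, .data$chrom) |>
    dplyr::summarise(start = min(.data$pos) - 1, end = max(.data$pos),
                     .groups = "drop")
  nested <- tidyr::nest(d, calls = c("pos", "call"))
  out <- dplyr::left_join(spans, nested, by = c("read_id", "chrom"))
  out |>
    dplyr::mutate(sample = sample, is_lambda = .data$chrom %in% lambda_contigs) |>
    dplyr::select("read_id", "sample", "chrom", "start", "end",
                  "is_lambda", "calls")
}

#' Write long-read methylation calls
#'
#' Inverse of [read_longread_calls()]: one row per call,
#' `read_id  chrom  pos  call`.
#'
#' @param reads Read tibble with a `calls` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_longread_calls <- function(reads, path) {
  flat <- tidyr::unnest(reads[, c("read_id", "chrom", "calls")], "calls")
  readr::write_tsv(flat[, c("read_id", "chrom", "pos", "call")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a domain set as BED
#'
#' Intervals are written 0-based half-open with the domain kind (and core
#' flag, when present) in the name column, ordered by the layout's
#' chromosome order then start.
#'
#' @param domains Tibble with `chrom`, `start`, `end` and optionally `kind`
#'   and `core` columns.
#' @param path Output path.
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return `path`, invisibly.
#' @export
write_domains <- function(domains, path, layout = NULL) {
  ord <- if (!is.null(layout)) layout$chromosomes$chrom else NULL
  header <- "#chrom\tstart\tend\tname"
  if (nrow(domains) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  d <- sort_intervals(domains, ord)
  name <- if ("kind" %in% names(d)) as.character(d$kind) else "domain"
  if ("core" %in% names(d)) name <- ifelse(d$core, paste0(name, ":core"), name)
  body <- sprintf("%s\t%s\t%s\t%s", d$chrom,
                  format(d$start, scientific = FALSE, trim = TRUE),
                  format(d$end, scientific = FALSE, trim = TRUE), name)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a domain BED file written by [write_domains()]
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start`, `end`, `kind`, `core`.
#' @export
read_domains <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), kind = character(),
                          core = logical()))
  }
  f <- strsplit(lines, "\t")
  m <- matrix(unlist(lapply(f, `[`, 1:4)), ncol = 4, byrow = TRUE)
  name <- ifelse(is.na(m[, 4]), "domain", m[, 4])
  tibble::tibble(chrom = m[, 1], start = as.double(m[, 2]),
                 end = as.double(m[, 3]),
                 kind = sub(":core$", "", name),
                 core = grepl(":core$", name))
}

#' Read integer copy-number bins (BED + copy-number column)
#'
#' @param path File with columns `chrom start end copy_number` and
#'   optionally a 5th `cell` column.
#' @return A tibble `cell`, `chrom`, `start`, `end`, `cn`.
#' @export
read_copy_number <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(lines)]
  f <- strsplit(lines, "[ \t]+")
  nf <- lengths(f)
  if (any(nf < 4)) stop("malformed copy-number line ", which(nf < 4)[1],
                        call. = FALSE)
  chrom <- vapply(f, `[`, "", 1)
  tibble::tibble(
    cell = ifelse(nf >= 5, vapply(f, function(x) x[5] %||% "cell", ""), "cell"),
    chrom = chrom,
    start = as.double(vapply(f, `[`, "", 2)),
    end = as.double(vapply(f, `[`, "", 3)),
    cn = as.double(vapply(f, `[`, "", 4))
  )
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: set name, description, then member genes, tab
#'   separated.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t")
  sets <- lapply(f, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(f, `[`, "", 1)
  sets
}

#' Cell-level sequencing QC
#'
#' A cell passes when it covers more than `qc_min_unique_cpgs` distinct CpG
#' sites at least once and its bisulfite conversion rate exceeds
#' `qc_min_conversion` (defaults: 4 million sites, 98%).
#'
#' @param calls Call tibble for one cell (columns `chrom`, `pos`).
#' @param conversion_rate Bisulfite conversion rate in \[0, 1\].
#' @param cfg A [pmd_config()].
#' @return A one-row tibble: `n_cpgs`, `conversion_rate`, `pass`.
#' @export
#' @examples
#' qc_cell(data.frame(chrom = "chr1", pos = 1:10), conversion_rate = 0.99)
qc_cell <- function(calls, conversion_rate, cfg = pmd_config()) {
  stopifnot(conversion_rate >= 0, conversion_rate <= 1)
  calls <- tibble::as_tibble(calls)
  n <- nrow(dplyr::distinct(calls, .data$chrom, .data$pos))
  tibble::tibble(
    n_cpgs = n,
    conversion_rate = conversion_rate,
    pass = n > cfg$qc_min_unique_cpgs & conversion_rate > cfg$qc_min_conversion
  )
}
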