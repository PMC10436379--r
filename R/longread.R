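#' Per-read PMD-restricted methylation
#'
#' For each genomic read, only CpG calls that fall inside a PMD interval
#' and outside any CpG island are eligible; the read's methylation is the
#' mean of its eligible binary calls. Lambda reads get no eligible calls.
#'
#' @param reads Read tibble (from [read_longread_calls()] or
#'   [generate_longreads()]).
#' @param pmds Interval tibble (`chrom`, `start`, `end`).
#' @param layout A [genome_layout()] supplying CGI intervals.
#'
#' @return `reads` with added columns `n_eligible` and `mean_meth`
#'   (`NA` when no call is eligible).
#' @export
read_methylation <- function(reads, pmds, layout) {
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0) {
    return(dplyr::mutate(reads, n_eligible = integer(), mean_meth = double()))
  }
  flat <- tidyr::unnest(
    dplyr::mutate(reads[, c("read_id", "chrom", "is_lambda", "calls")],
                  .row = dplyr::row_number()),
    "calls"
  )
  elig <- !flat$is_lambda &
    positions_in_intervals(flat$chrom, flat$pos, pmds) &
    !positions_in_intervals(flat$chrom, flat$pos, layout$cgi)
  stats <- flat |>
    dplyr::mutate(elig = elig) |>
    dplyr::group_by(.data$.row) |>
    dplyr::summarise(n_eligible = sum(.data$elig),
                     mean_meth = ifelse(sum(.data$elig) > 0,
                                        mean(.data$call[.data$elig]),
                                        NA_real_),
                     .groups = "drop")
  reads$n_eligible <- 0L
  reads$mean_meth <- NA_real_
  reads$n_eligible[stats$.row] <- as.integer(stats$n_eligible)
  reads$mean_meth[stats$.row] <- stats$mean_meth
  reads
}

#' Filter and classify long reads
#'
#' A read passes when it carries at least `cfg$min_cpgs_per_read` (30)
#' eligible CpG calls; a passing read is hypomethylated when its mean
#' eligible methylation is below `cfg$read_hypo_threshold`.
#'
#' @inheritParams read_methylation
#' @param cfg A [pmd_config()].
#' @return `reads` with added `n_eligible`, `mean_meth`, `passes`, `hypo`.
#' @export
filter_and_classify <- function(reads, pmds, layout, cfg = pmd_config()) {
  r <- read_methylation(reads, pmds, layout)
  r$passes <- r$n_eligible >= cfg$min_cpgs_per_read
  r$hypo <- r$passes & !is.na(r$mean_meth) &
    r$mean_meth < cfg$read_hypo_threshold
  r
}

#' Per-sample hypomethylation signal with run QC
#'
#' Computes the sample's lambda spike-in methylation (methylated fraction
#' over all lambda-read calls), counts PMD-aligned reads (>= 1 eligible
#' call) and passing reads (>= 30 eligible calls), and reports
#' signal = 100 x hypomethylated / passing. The sample passes QC when
#' lambda methylation is below `cfg$lambda_max` (1%) and the PMD-aligned
#' read count reaches the cohort minimum (300 metastatic, 400 localized);
#' the signal is reported only for QC-passing samples.
#'
#' @inheritParams filter_and_classify
#' @param cohort `"metastatic"`, `"localized"`, or `"healthy"`.
#' @return A one-row tibble: `sample`, `cohort`, `n_reads_in_pmds`,
#'   `n_passing`, `n_hypo`, `lambda_meth`, `qc_pass`, `signal`.
#' @export
sample_signal <- function(reads, cohort = c("metastatic", "localized",
                                            "healthy"),
                          pmds, layout, cfg = pmd_config()) {
  cohort <- match.arg(cohort)
  r <- filter_and_classify(reads, pmds, layout, cfg)
  lam <- r[r$is_lambda, ]
  lambda_meth <- if (nrow(lam) > 0) {
    calls <- dplyr::bind_rows(lam$calls)
    mean(calls$call)
  } else NA_real_
  gen <- r[!r$is_lambda, ]
  n_in_pmds <- sum(gen$n_eligible >= 1)
  n_passing <- sum(gen$passes)
  n_hypo <- sum(gen$hypo)
  min_reads <- switch(cohort,
                      metastatic = cfg$min_reads_metastatic,
                      localized = cfg$min_reads_localized,
                      healthy = cfg$min_reads_healthy)
  qc <- !is.na(lambda_meth) && lambda_meth < cfg$lambda_max &&
    n_in_pmds >= min_reads
  tibble::tibble(
    sample = if (nrow(r) > 0) r$sample[1] else NA_character_,
    cohort = cohort,
    n_reads_in_pmds = n_in_pmds, n_passing = n_passing, n_hypo = n_hypo,
    lambda_meth = lambda_meth, qc_pass = qc,
    signal = if (qc && n_passing > 0) 100 * n_hypo / n_passing else NA_real_
  )
}

#' Compare cohort hypomethylation signals
#'
#' Two-tailed equal-variance two-sample t-tests on per-sample signal
#' percentages of each cancer cohort against the reference (healthy)
#' cohort, on QC-passing samples only. Each group's maximum signal is
#' reported, along with the count of cohort samples whose signal exceeds
#' the reference maximum (the "above all healthy donors" positivity
#' rule).
#'
#' @param signals Tibble of [sample_signal()] rows.
#' @param ref Reference cohort name.
#' @return A tibble of class `pmd_cohort`: one row per contrast with
#'   `cohort`, `n`, `n_ref`, `mean`, `mean_ref`, `max`, `max_ref`,
#'   `t`, `p`, `n_above_ref_max`.
#' @export
cohort_compare <- function(signals, ref = "healthy") {
  s <- signals[signals$qc_pass & !is.na(signals$signal), ]
  x_ref <- s$signal[s$cohort == ref]
  if (length(x_ref) < 2) stop("fewer than 2 QC-passing reference samples",
                              call. = FALSE)
  rows <- lapply(setdiff(unique(s$cohort), ref), function(g) {
    x <- s$signal[s$cohort == g]
    if (length(x) < 2) stop("fewer than 2 QC-passing samples in '", g, "'",
                            call. = FALSE)
    n1 <- length(x); n2 <- length(x_ref)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(x_ref)) / (n1 + n2 - 2)
    if (sp2 == 0) {
      warning("degenerate variance in contrast '", g, "'; p set to 1",
              call. = FALSE)
      tstat <- 0; p <- 1
    } else {
      tstat <- (mean(x) - mean(x_ref)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * pt(-abs(tstat), n1 + n2 - 2)
    }
    tibble::tibble(cohort = g, n = n1, n_ref = n2,
                   mean = mean(x), mean_ref = mean(x_ref),
                   max = max(x), max_ref = max(x_ref),
                   t = tstat, p = p,
                   n_above_ref_max = sum(x > max(x_ref)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pmd_cohort", class(out))
  out
}

#' @rdname cohort_compare
#' @param x A `pmd_cohort` object.
#' @param ... Unused.
#' @export
tidy.pmd_cohort <- function(x, ...) tibble::as_tibble(x)

#' Spike-in precision-recall model of read classification
#'
#' Scores each labelled read by 1 - mean eligible methylation (higher =
#' more tumor-like) and sweeps every observed score as a classification
#' threshold, yielding a precision-recall curve per stratum; the area is
#' the trapezoid over the swept points. Strata come from a `stratum`
#' column when present (e.g. reads generated at ~5/10/30/50 CpGs per
#' read), otherwise all reads form one stratum. No minimum-CpG filter is
#' applied here: the model quantifies how precision grows with
#' CpGs per read.
#'
#' @inheritParams read_methylation
#' @param min_eligible Reads with fewer eligible calls are excluded
#'   (default 1: a read must carry some signal to be scored).
#' @return An object of class `pmd_pr`: list with `curves` (tibble
#'   `stratum`, `threshold`, `recall`, `precision`) and `auc` (tibble
#'   `stratum`, `auc`, `n_tumor`, `n_normal`).
#' @export
spikein_pr_model <- function(reads, pmds, layout, min_eligible = 1L) {
  stopifnot("origin" %in% names(reads))
  r <- read_methylation(reads[!reads$is_lambda, ], pmds, layout)
  r <- r[r$n_eligible >= min_eligible, ]
  if (!"stratum" %in% names(r)) r$stratum <- "all"
  if (length(unique(r$origin)) < 2) {
    stop("need both tumor and normal reads to build a PR curve",
         call. = FALSE)
  }
  curves <- list(); aucs <- list()
  for (st in unique(r$stratum)) {
    d <- r[r$stratum == st, ]
    y <- d$origin == "tumor"
    if (sum(y) == 0 || sum(!y) == 0) {
      stop("stratum '", st, "' lacks one of the classes", call. = FALSE)
    }
    score <- 1 - d$mean_meth
    ord <- order(score, decreasing = TRUE)
    y <- y[ord]; score <- score[ord]
    tp <- cumsum(y)
    fp <- cumsum(!y)
    # one point per distinct score (threshold = that score, rule >=)
    last <- !duplicated(score, fromLast = TRUE)
    prec <- tp[last] / (tp[last] + fp[last])
    rec <- tp[last] / sum(y)
    thr <- score[last]
    curves[[st]] <- tibble::tibble(stratum = st, threshold = thr,
                                   recall = rec, precision = prec)
    rr <- c(0, rec); pp <- c(prec[1], prec)
    auc <- sum(diff(rr) * (head(pp, -1) + tail(pp, -1)) / 2)
    aucs[[st]] <- tibble::tibble(stratum = st, auc = auc,
                                 n_tumor = sum(y), n_normal = sum(!y))
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 auc = dplyr::bind_rows(aucs)),
            class = "pmd_pr")
}

#' @export
print.pmd_pr <- function(x, ...) {
  cat("<pmd_pr>\n")
  print(x$auc, ...)
  invisible(x)
}

#' @rdname spikein_pr_model
#' @param x,object A `pmd_pr` object.
#' @param ... Unused.
#' @export
tidy.pmd_pr <- function(x, ...) x$curves

#' @rdname spikein_pr_model
#' @export
glance.pmd_pr <- function(x, ...) x$auc

#' @rdname spikein_pr_model
#' @export
autoplot.pmd_pr <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$recall, y = .data$precision,
                               colour = .data$stratum)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = "Spike-in read classification",
                  x = "recall", y = "precision", colour = "CpGs/read")
}
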