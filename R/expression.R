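#' Screen domain-resident genes for differential expression
#'
#' The expression screen applied to genes residing in PMDs or PMIs: genes
#' whose 95th-percentile expression falls below 1 (FPKM-like units) are
#' discarded; the rest are tested with a two-tailed equal-variance
#' two-sample t-test (tumor vs normal), p-values are converted to
#' Benjamini-Hochberg FDR estimates across the tested genes, and genes
#' with FDR below `cfg$de_fdr` (0.1) are called differentially expressed.
#'
#' @param expr Genes x samples nonnegative matrix (rownames = genes).
#' @param groups Named vector mapping sample columns to
#'   `"tumor"`/`"normal"` (>= 2 samples each).
#' @param genes Optional character vector restricting the screen to
#'   domain-resident genes.
#' @param cfg A [pmd_config()].
#'
#' @return A tibble with one row per input gene: `gene`, `kept`,
#'   `mean_tumor`, `mean_normal`, `direction` (sign of tumor - normal),
#'   `t`, `p`, `fdr`, `significant`.
#' @export
screen_domain_genes <- function(expr, groups, genes = NULL,
                                cfg = pmd_config()) {
  stopifnot(is.matrix(expr), all(expr >= 0, na.rm = TRUE),
            all(names(groups) %in% colnames(expr)))
  tum <- names(groups)[groups == "tumor"]
  nor <- names(groups)[groups == "normal"]
  if (length(tum) < 2 || length(nor) < 2) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  if (!is.null(genes)) expr <- expr[intersect(genes, rownames(expr)), ,
                                    drop = FALSE]
  q95 <- apply(expr[, c(tum, nor), drop = FALSE], 1, quantile,
               probs = cfg$de_expr_floor_percentile, na.rm = TRUE)
  kept <- q95 >= cfg$de_expr_floor

  xt <- expr[, tum, drop = FALSE]
  xn <- expr[, nor, drop = FALSE]
  n1 <- length(tum); n2 <- length(nor)
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- apply(xt, 1, var); v2 <- apply(xn, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- !is.na(sp2) & sp2 == 0
  if (any(degenerate & kept)) {
    message(sum(degenerate & kept), " gene(s) with zero variance in both ",
            "groups assigned p = 1")
  }
  tstat[degenerate] <- 0
  p[degenerate] <- 1

  out <- tibble::tibble(
    gene = rownames(expr), kept = unname(kept),
    mean_tumor = unname(m1), mean_normal = unname(m2),
    direction = unname(sign(m1 - m2)),
    t = unname(ifelse(kept, tstat, NA_real_)),
    p = unname(ifelse(kept, p, NA_real_))
  )
  out$fdr <- NA_real_
  out$fdr[out$kept] <- p.adjust(out$p[out$kept], method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < cfg$de_fdr
  out
}

#' Hypergeometric gene-set enrichment (hGSEA)
#'
#' Upper-tail overlap probability of a selected gene list against each
#' gene set within a universe: with N = |universe|, m = |set within
#' universe|, n = |selected| and k = |selected within set|, the
#' enrichment p-value is P(X >= k) for X hypergeometric(m, N - m, n).
#' Benjamini-Hochberg FDR across sets is reported alongside the raw p.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`; genes outside it are dropped with a message).
#' @param universe Character vector, the gene universe.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#'
#' @return A tibble `set`, `set_size`, `overlap`, `expected`, `p`, `fdr`.
#' @export
#' @examples
#' hgsea(c("a", "b"), letters[1:10], list(s1 = c("a", "b", "c")))
hgsea <- function(selected, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  selected <- unique(selected)
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    message(length(outside), " selected gene(s) outside the universe dropped")
    selected <- intersect(selected, universe)
  }
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    m <- length(s)
    k <- length(intersect(selected, s))
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = m, overlap = k,
                   expected = n * m / N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}
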