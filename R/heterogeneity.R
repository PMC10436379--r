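#' Interval-Jaccard heterogeneity
#'
#' Pairwise bp-level Jaccard indices between the hypomethylated interval
#' sets of cells, summarised as the mean over unordered within-group
#' pairs. A higher mean indicates less heterogeneity. A pair with one
#' empty set scores 0; two empty sets score 1 (reported via a message).
#'
#' @param sets Tibble `cell`, `chrom`, `start`, `end` of per-cell
#'   hypomethylated intervals (cells with no intervals may be absent; list
#'   them in `groups` to include them as empty sets).
#' @param groups Named vector mapping cell ids to group labels.
#'
#' @return A list: `pairs` (tibble `group`, `cell1`, `cell2`, `jaccard`)
#'   and `summary` (tibble `group`, `mean_jaccard`, `n_pairs`).
#' @export
jaccard_heterogeneity <- function(sets, groups) {
  sets <- tibble::as_tibble(sets)
  cells <- names(groups)
  empty_cells <- setdiff(cells, unique(sets$cell))
  if (length(empty_cells) > 0) {
    message(length(empty_cells), " cell(s) with empty interval sets")
  }
  pairs <- list()
  for (g in unique(groups)) {
    members <- cells[groups == g]
    if (length(members) < 2) {
      stop("group '", g, "' has fewer than 2 cells", call. = FALSE)
    }
    cmb <- utils::combn(members, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- sets[sets$cell == cmb[1, k], c("chrom", "start", "end")]
      b <- sets[sets$cell == cmb[2, k], c("chrom", "start", "end")]
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        group = g, cell1 = cmb[1, k], cell2 = cmb[2, k],
        jaccard = interval_jaccard(a, b)
      )
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  summary <- pairs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_jaccard = mean(.data$jaccard),
                     n_pairs = dplyr::n(), .groups = "drop")
  list(pairs = pairs, summary = summary)
}

#' Correlation heterogeneity with jackknife standard errors
#'
#' Mean pairwise correlation between cells of a group over features
#' non-missing in both cells, with a leave-one-cell-out jackknife
#' standard error of that mean. Pairs sharing fewer than 2 features are
#' skipped with a message.
#'
#' @param m Cells x features numeric matrix (rownames = cell ids).
#' @param groups Named vector mapping cell ids to group labels (>= 3 cells
#'   per group).
#' @param method Correlation coefficient: `"pearson"` (default) or
#'   `"spearman"`.
#'
#' @return A tibble `group`, `mean_cor`, `jackknife_se`, `n_cells`,
#'   `n_pairs`.
#' @export
correlation_heterogeneity <- function(m, groups,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), !is.null(rownames(m)),
            all(names(groups) %in% rownames(m)))
  pair_cor <- function(a, b) {
    ok <- !is.na(m[a, ]) & !is.na(m[b, ])
    if (sum(ok) < 2) return(NA_real_)
    cor(m[a, ok], m[b, ok], method = method)
  }
  rows <- lapply(unique(groups), function(g) {
    members <- names(groups)[groups == g]
    if (length(members) < 3) {
      stop("group '", g, "' has fewer than 3 cells", call. = FALSE)
    }
    cmb <- utils::combn(members, 2)
    pc <- vapply(seq_len(ncol(cmb)),
                 function(k) pair_cor(cmb[1, k], cmb[2, k]), double(1))
    if (anyNA(pc)) {
      message(sum(is.na(pc)), " pair(s) skipped (fewer than 2 shared features)")
    }
    mean_all <- mean(pc, na.rm = TRUE)
    n <- length(members)
    theta <- vapply(members, function(drop) {
      keep <- !(cmb[1, ] == drop | cmb[2, ] == drop)
      mean(pc[keep], na.rm = TRUE)
    }, double(1))
    se <- sqrt((n - 1) / n * sum((theta - mean(theta))^2))
    tibble::tibble(group = g, mean_cor = mean_all, jackknife_se = se,
                   n_cells = n, n_pairs = sum(!is.na(pc)))
  })
  dplyr::bind_rows(rows)
}
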