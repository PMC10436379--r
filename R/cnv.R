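#' Copy-number aberration score
#'
#' For a diploid genome, the score of a cell is the genome-wide average of
#' |copy number - 2| over its bins, weighted by bin length so ragged
#' terminal bins contribute proportionally. Diploid cells score 0.
#'
#' @param profile Tibble `chrom`, `start`, `end`, `cn`, with an optional
#'   `cell` column (one score per cell).
#'
#' @return A tibble `cell`, `cnv_score`.
#' @export
#' @examples
#' cnv_score(data.frame(chrom = "chr1", start = 0, end = 5e6, cn = 2))
cnv_score <- function(profile) {
  profile <- tibble::as_tibble(profile)
  if (nrow(profile) == 0) stop("empty copy-number profile", call. = FALSE)
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(profile)))
  if (any(profile$cn < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  if (!"cell" %in% names(profile)) profile$cell <- "cell"
  profile |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      cnv_score = sum(abs(.data$cn - 2) * (.data$end - .data$start)) /
        sum(.data$end - .data$start),
      .groups = "drop"
    )
}
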