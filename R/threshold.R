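#' Select per-source hypomethylation thresholds
#'
#' Implements the valley rule: the window-methylation density of each
#' source is estimated with a Gaussian kernel (bandwidth
#' `cfg$density_bw`) on an even grid over \[0, 1\]. Modes are local maxima
#' whose topographic prominence reaches `cfg$mode_prominence` of the
#' global maximum; the distribution is bimodal when at least two
#' qualifying modes are separated by `cfg$mode_separation` or more. For a
#' bimodal source the threshold is the density minimum strictly between
#' the two dominant modes (ties broken toward lower methylation); for a
#' unimodal source it is the fixed fallback, 60%.
#'
#' @param track Window track from [build_window_track()] (one or more
#'   sources).
#' @param cfg A [pmd_config()].
#'
#' @return A tibble of class `pmd_threshold`: one row per source with
#'   `source`, `modality`, `threshold`, `mode_lo`, `mode_hi`,
#'   `n_windows`; the per-source density curves are kept in
#'   `attr(x, "density")`.
#' @export
#' @examples
#' sim <- generate_methylome(synth_normal_spec(seed = 1))
#' track <- build_window_track(sim$calls, sim$layout)
#' select_threshold(track)
select_threshold <- function(track, cfg = pmd_config()) {
  stopifnot(all(c("source", "meth") %in% names(track)))
  dens <- list()
  rows <- lapply(unique(track$source), function(src) {
    x <- track$meth[track$source == src]
    x <- x[!is.na(x)]
    if (length(x) < cfg$min_windows) {
      stop("source '", src, "' has ", length(x), " scored windows; at least ",
           cfg$min_windows, " are required to estimate a threshold",
           call. = FALSE)
    }
    d <- density(x, bw = cfg$density_bw, from = 0, to = 1, n = cfg$density_n)
    dens[[src]] <<- tibble::tibble(grid = d$x, density = d$y)
    modes <- find_modes(d$x, d$y)
    qual <- modes[modes$prominence >= cfg$mode_prominence * max(d$y), ]
    bimodal <- FALSE
    m_lo <- m_hi <- NA_real_
    thr <- cfg$fallback_threshold
    if (nrow(qual) >= 2) {
      top2 <- qual[order(-qual$height), ][1:2, ]
      if (abs(top2$x[1] - top2$x[2]) >= cfg$mode_separation) {
        bimodal <- TRUE
        m_lo <- min(top2$x); m_hi <- max(top2$x)
        ilo <- which.min(abs(d$x - m_lo)); ihi <- which.min(abs(d$x - m_hi))
        between <- (ilo + 1):(ihi - 1)
        thr <- d$x[between[which.min(d$y[between])]]
      }
    }
    tibble::tibble(source = src,
                   modality = if (bimodal) "bimodal" else "unimodal",
                   threshold = thr, mode_lo = m_lo, mode_hi = m_hi,
                   n_windows = length(x))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "density") <- dens
  class(out) <- c("pmd_threshold", class(out))
  out
}

# Local maxima of a density grid with topographic prominence.
find_modes <- function(x, y) {
  n <- length(y)
  i <- 2:(n - 1)
  peaks <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  if (length(peaks) == 0) {
    return(tibble::tibble(idx = integer(), x = double(), height = double(),
                          prominence = double()))
  }
  prom <- vapply(peaks, function(p) {
    higher <- which(y > y[p])
    if (length(higher) == 0) return(y[p])
    leftH <- higher[higher < p]
    rightH <- higher[higher > p]
    sl <- if (length(leftH)) min(y[max(leftH):p]) else -Inf
    sr <- if (length(rightH)) min(y[p:min(rightH)]) else -Inf
    y[p] - max(sl, sr)
  }, double(1))
  tibble::tibble(idx = peaks, x = x[peaks], height = y[peaks],
                 prominence = prom)
}

#' @export
print.pmd_threshold <- function(x, ...) {
  cat("<pmd_threshold>\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' @rdname select_threshold
#' @param x A `pmd_threshold` object.
#' @param ... Unused.
#' @export
tidy.pmd_threshold <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname select_threshold
#' @export
glance.pmd_threshold <- function(x, ...) {
  tibble::tibble(n_sources = nrow(x),
                 n_bimodal = sum(x$modality == "bimodal"),
                 n_unimodal = sum(x$modality == "unimodal"))
}

#' @rdname select_threshold
#' @param object A `pmd_threshold` object.
#' @export
autoplot.pmd_threshold <- function(object, ...) {
  dens <- attr(object, "density")
  dd <- dplyr::bind_rows(lapply(names(dens), function(s) {
    dplyr::mutate(dens[[s]], source = s)
  }))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = tibble::as_tibble(object),
      mapping = ggplot2::aes(xintercept = .data$threshold),
      linetype = "dashed", colour = "blue"
    ) +
    ggplot2::facet_wrap(~source, scales = "free_y") +
    ggplot2::labs(x = "window methylation", y = "density",
                  title = "Window methylation density and thresholds")
}
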