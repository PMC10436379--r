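#' Synthetic methylome specification
#'
#' Describes the generative model behind every synthetic input the pipeline
#' consumes. The defaults emulate the study conditions: a background
#' methylome whose per-site means are Beta(16, 4) (mean 0.80, the "single
#' peak near 80%" of normal cells), planted PMD intervals whose state mean
#' is drawn uniform on \[0.20, 0.40\], PMIs nested inside PMDs that revert
#' to background, sparse binary single-cell calls at 30% site coverage from
#' 10 cells, CpGs every ~100 bp (5x denser inside CpG islands), ~10-kb long
#' reads, a 1% tumor spike fraction, and a 0.5% lambda error rate.
#'
#' @param genome Tibble `chrom`, `length`; default two 10-Mb chromosomes.
#' @param true_pmds Planted PMD intervals (`chrom`, `start`, `end`,
#'   optional `meth`); `meth` is drawn uniform \[0.20, 0.40\] per interval
#'   when absent.
#' @param true_pmis Planted PMIs; must lie strictly inside planted PMDs.
#' @param background Beta shape parameters of per-site background
#'   methylation means.
#' @param pmd_state_range Range the per-PMD state mean is drawn from when
#'   `true_pmds$meth` is absent.
#' @param spacing Mean inter-CpG distance, bp.
#' @param cgi_density CpG islands per bp (default one per 200 kb).
#' @param cgi_size Mean CGI width, bp.
#' @param cgi_spacing_factor CpG density multiplier inside CGIs.
#' @param gaps Optional assembly-gap intervals for the layout.
#' @param n_cells Cells generated for the source.
#' @param coverage Per-cell probability that a site is observed.
#' @param source Source label attached to all cells.
#' @param read_length Mean long-read length, bp.
#' @param spike_fraction Default tumor-read fraction for spike-in mixtures.
#' @param lambda_error Per-call methylation probability on lambda spike-in.
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, its arguments).
#'
#' @return A list of class `synth_spec`.
#' @export
#' @examples
#' sp <- synth_spec(seed = 1)
synth_spec <- function(genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                               length = c(1e7, 1e7)),
                       true_pmds = NULL,
                       true_pmis = NULL,
                       background = c(16, 4),
                       pmd_state_range = c(0.20, 0.40),
                       spacing = 100,
                       cgi_density = 1 / 200000,
                       cgi_size = 1000,
                       cgi_spacing_factor = 5,
                       gaps = NULL,
                       n_cells = 10L,
                       coverage = 0.3,
                       source = "source1",
                       read_length = 10000,
                       spike_fraction = 0.01,
                       lambda_error = 0.005,
                       seed = 1L) {
  genome <- tibble::as_tibble(genome)
  spec <- mget(names(formals()))
  stopifnot(all(genome$length > 0), coverage >= 0, coverage <= 1,
            spike_fraction >= 0, spike_fraction <= 1,
            lambda_error >= 0, lambda_error <= 1)
  if (!is.null(true_pmds)) {
    true_pmds <- check_intervals(true_pmds, genome)
    m <- merge_intervals(true_pmds)
    if (nrow(m) != nrow(true_pmds)) {
      stop("planted PMDs overlap each other", call. = FALSE)
    }
  }
  if (!is.null(true_pmis)) {
    if (is.null(true_pmds)) stop("PMIs require planted PMDs", call. = FALSE)
    true_pmis <- check_intervals(true_pmis, genome)
    inside <- vapply(seq_len(nrow(true_pmis)), function(i) {
      any(true_pmds$chrom == true_pmis$chrom[i] &
            true_pmds$start < true_pmis$start[i] &
            true_pmds$end > true_pmis$end[i])
    }, logical(1))
    if (!all(inside)) {
      stop("planted PMIs must lie strictly inside a planted PMD", call. = FALSE)
    }
  }
  spec$true_pmds <- true_pmds
  spec$true_pmis <- true_pmis
  structure(spec, class = "synth_spec")
}

#' Canned specs: a unimodal normal source and a bimodal tumor source
#'
#' `synth_normal_spec()` plants nothing, so the window-methylation
#' distribution is unimodal near 0.80. `synth_tumor_spec()` plants two
#' 3-Mb PMDs covering 30% of the 20-Mb toy genome; with `with_pmi = TRUE`
#' the first PMD is enlarged and carries a nested 2-Mb PMI. Few, large
#' domains are planted because 100-kb windowing blurs each domain edge by
#' roughly half a window, which bounds the attainable boundary precision.
#'
#' @param seed Integer seed.
#' @param source Source label.
#' @param with_pmi Plant a PMI inside the first PMD.
#' @return A [synth_spec()].
#' @export
synth_normal_spec <- function(seed = 1L, source = "normal1") {
  synth_spec(seed = seed, source = source)
}

#' @rdname synth_normal_spec
#' @export
synth_tumor_spec <- function(seed = 1L, source = "tumor1", with_pmi = FALSE) {
  if (with_pmi) {
    pmds <- tibble::tibble(
      chrom = c("chr1", "chr2"),
      start = c(1.0e6, 2.0e6),
      end   = c(5.4e6, 4.0e6)
    )
    pmis <- tibble::tibble(chrom = "chr1", start = 2.7e6, end = 4.7e6)
  } else {
    pmds <- tibble::tibble(
      chrom = c("chr1", "chr2"),
      start = c(1e6, 2e6),
      end   = c(4e6, 5e6)
    )
    pmis <- NULL
  }
  synth_spec(true_pmds = pmds, true_pmis = pmis, seed = seed, source = source)
}

# CpG site positions (1-based) for one chromosome: geometric spacing plus
# extra density inside CGIs.
sim_sites <- function(len, spacing, cgi, factor) {
  n_guess <- ceiling(1.2 * len / spacing) + 100
  gaps <- rgeom(n_guess, prob = 1 / spacing) + 1
  pos <- cumsum(gaps)
  pos <- pos[pos <= len]
  if (!is.null(cgi) && nrow(cgi) > 0 && factor > 1) {
    extra_n <- ceiling(sum(cgi$end - cgi$start) * (factor - 1) / spacing)
    w <- (cgi$end - cgi$start) / sum(cgi$end - cgi$start)
    pick <- sample.int(nrow(cgi), extra_n, replace = TRUE, prob = w)
    extra <- floor(cgi$start[pick] + runif(extra_n) * (cgi$end[pick] - cgi$start[pick])) + 1
    pos <- c(pos, extra)
  }
  sort(unique(pos))
}

#' Generate a synthetic single-cell methylome
#'
#' Each CpG site carries a methylation probability: the planted PMD state
#' mean inside a PMD, and a per-site Beta draw from the background
#' distribution elsewhere (including inside planted PMIs, which revert to
#' background). Every cell observes each site independently with the
#' spec's coverage probability and emits one Bernoulli call at the site's
#' probability.
#'
#' @param spec A [synth_spec()].
#' @return A list with `layout` ([genome_layout()]), `calls` (tibble as from
#'   [read_cpg_calls()]), `truth` (tibble `chrom`, `start`, `end`, `kind`
#'   in PMD/PMI, `meth` for PMDs; PMD rows are the planted hypomethylated
#'   intervals, i.e. planted PMDs minus their PMIs), and `sites`
#'   (per-site `chrom`, `pos`, `p`).
#' @export
#' @examples
#' sim <- generate_methylome(synth_normal_spec(seed = 7))
#' nrow(sim$calls)
generate_methylome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::local_seed(spec$seed)

  # CpG islands: PMDs are gene-poor and CGI-poor, so islands are placed in
  # the complement of the planted PMDs (uniformly when nothing is planted).
  cgi <- dplyr::bind_rows(lapply(seq_len(nrow(spec$genome)), function(i) {
    ch <- spec$genome$chrom[i]
    len <- spec$genome$length[i]
    n <- max(0L, round(len * spec$cgi_density))
    if (n == 0) return(NULL)
    w <- pmax(200, round(rlnorm(n, log(spec$cgi_size), 0.3)))
    open <- tibble::tibble(chrom = ch, start = 0, end = len)
    if (!is.null(spec$true_pmds) && nrow(spec$true_pmds) > 0) {
      pm <- spec$true_pmds[spec$true_pmds$chrom == ch, ]
      if (nrow(pm) > 0) {
        bounds <- sort(c(0, pm$start, pm$end, len))
        seg <- tibble::tibble(chrom = ch,
                              start = bounds[seq(1, length(bounds), 2)],
                              end = bounds[seq(2, length(bounds), 2)])
        open <- seg[seg$end > seg$start, ]
      }
    }
    seg_len <- open$end - open$start
    pick <- sample.int(nrow(open), n, replace = TRUE,
                       prob = seg_len / sum(seg_len))
    s <- floor(open$start[pick] +
                 runif(n) * pmax(1, open$end[pick] - open$start[pick] - w))
    tibble::tibble(chrom = ch, start = s, end = pmin(s + w, len))
  }))
  layout <- genome_layout(spec$genome, cgi = cgi, gaps = spec$gaps)

  # planted truth
  pmds <- spec$true_pmds
  if (!is.null(pmds) && nrow(pmds) > 0) {
    pmds <- sort_intervals(pmds, spec$genome$chrom)
    if (!"meth" %in% names(pmds)) {
      pmds$meth <- runif(nrow(pmds), spec$pmd_state_range[1],
                         spec$pmd_state_range[2])
    }
  } else {
    pmds <- tibble::tibble(chrom = character(), start = double(),
                           end = double(), meth = double())
  }
  pmis <- spec$true_pmis %||%
    tibble::tibble(chrom = character(), start = double(), end = double())

  # sites and their methylation probabilities
  sites <- dplyr::bind_rows(lapply(seq_len(nrow(spec$genome)), function(i) {
    ch <- spec$genome$chrom[i]
    pos <- sim_sites(spec$genome$length[i], spec$spacing,
                     layout$cgi[layout$cgi$chrom == ch, ],
                     spec$cgi_spacing_factor)
    tibble::tibble(chrom = ch, pos = pos)
  }))
  p <- rbeta(nrow(sites), spec$background[1], spec$background[2])
  if (nrow(pmds) > 0) {
    for (i in seq_len(nrow(pmds))) {
      in_pmd <- sites$chrom == pmds$chrom[i] &
        sites$pos > pmds$start[i] & sites$pos <= pmds$end[i]
      p[in_pmd] <- pmds$meth[i]
    }
  }
  if (nrow(pmis) > 0) {
    in_pmi <- positions_in_intervals(sites$chrom, sites$pos, pmis)
    p[in_pmi] <- rbeta(sum(in_pmi), spec$background[1], spec$background[2])
  }
  sites$p <- p

  # per-cell sparse binary calls
  calls <- dplyr::bind_rows(lapply(seq_len(spec$n_cells), function(k) {
    obs <- which(runif(nrow(sites)) < spec$coverage)
    if (length(obs) == 0) return(NULL)
    tibble::tibble(
      cell = sprintf("%s_cell%02d", spec$source, k),
      source = spec$source,
      chrom = sites$chrom[obs],
      pos = sites$pos[obs],
      meth = as.double(rbinom(length(obs), 1, sites$p[obs])),
      total = 1
    )
  }))
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- tibble::tibble(cell = character(), source = character(),
                            chrom = character(), pos = double(),
                            meth = double(), total = double())
  }

  # truth: hypomethylated intervals = PMDs minus nested PMIs
  truth_pmd <- pmds
  if (nrow(pmis) > 0 && nrow(pmds) > 0) {
    pieces <- lapply(seq_len(nrow(pmds)), function(i) {
      sub <- pmis[pmis$chrom == pmds$chrom[i] &
                    pmis$start >= pmds$start[i] & pmis$end <= pmds$end[i], ]
      if (nrow(sub) == 0) return(pmds[i, ])
      sub <- sub[order(sub$start), ]
      bounds <- c(pmds$start[i], rbind(sub$start, sub$end), pmds$end[i])
      starts <- bounds[seq(1, length(bounds), by = 2)]
      ends <- bounds[seq(2, length(bounds), by = 2)]
      keep <- ends > starts
      tibble::tibble(chrom = pmds$chrom[i], start = starts[keep],
                     end = ends[keep], meth = pmds$meth[i])
    })
    truth_pmd <- dplyr::bind_rows(pieces)
  }
  truth <- dplyr::bind_rows(
    dplyr::mutate(truth_pmd, kind = "PMD"),
    dplyr::mutate(pmis, kind = "PMI", meth = NA_real_)
  )
  list(layout = layout, calls = calls,
       truth = if (nrow(truth)) sort_intervals(truth, spec$genome$chrom) else truth,
       sites = sites)
}

#' Generate labelled long reads over PMDs
#'
#' Reads are placed uniformly (length-weighted) inside the supplied PMD
#' intervals. Each read is tumor-origin with probability `tumor_fraction`;
#' tumor reads emit calls at the PMD state mean, normal reads at a per-call
#' background Beta draw. Lambda spike-in reads emit calls at the spec's
#' lambda error rate. True origins are kept for precision-recall scoring.
#'
#' @param spec A [synth_spec()].
#' @param pmds Interval tibble (`chrom`, `start`, `end`, optional `meth`).
#' @param n_reads Number of genomic reads (> 0).
#' @param tumor_fraction Probability a read is tumor-origin.
#' @param cpgs_per_read Calls per read: a single value, a vector sampled
#'   from, or `NULL` to draw Poisson(read_length / spacing).
#' @param n_lambda Number of lambda control reads.
#' @param lambda_calls Calls per lambda read.
#'
#' @return A read tibble as from [read_longread_calls()], plus an `origin`
#'   column (`"tumor"`, `"normal"`, or `"lambda"`).
#' @export
generate_longreads <- function(spec, pmds, n_reads, tumor_fraction,
                               cpgs_per_read = NULL, n_lambda = 0L,
                               lambda_calls = 500L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (n_reads <= 0) stop("`n_reads` must be positive", call. = FALSE)
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1, nrow(pmds) > 0)
  withr::local_seed(spec$seed)
  if (!"meth" %in% names(pmds)) pmds$meth <- 0.30

  n_calls <- if (is.null(cpgs_per_read)) {
    pmax(1L, rpois(n_reads, spec$read_length / spec$spacing))
  } else if (length(cpgs_per_read) == 1) {
    rep(as.integer(cpgs_per_read), n_reads)
  } else {
    sample(as.integer(cpgs_per_read), n_reads, replace = TRUE)
  }
  w <- (pmds$end - pmds$start) / sum(pmds$end - pmds$start)
  iv <- sample.int(nrow(pmds), n_reads, replace = TRUE, prob = w)
  span <- n_calls * spec$spacing
  lo <- pmds$start[iv]
  hi <- pmax(lo + 1, pmds$end[iv] - span)
  start0 <- floor(lo + runif(n_reads) * (hi - lo))
  origin <- ifelse(runif(n_reads) < tumor_fraction, "tumor", "normal")

  # flat call table for all reads at once, then nest per read
  ridx <- rep(seq_len(n_reads), n_calls)
  total <- length(ridx)
  gaps <- rgeom(total, 1 / spec$spacing) + 1
  cs <- cumsum(gaps)
  first <- cumsum(c(1, head(n_calls, -1)))
  within <- cs - rep(cs[first] - gaps[first], n_calls)
  pos <- start0[ridx] + within
  p <- ifelse(origin[ridx] == "tumor", pmds$meth[iv[ridx]],
              rbeta(total, spec$background[1], spec$background[2]))
  flat <- tibble::tibble(
    read_id = sprintf("read%06d", ridx),
    chrom = pmds$chrom[iv[ridx]],
    pos = as.double(pos),
    call = as.double(rbinom(total, 1, p))
  )
  out <- longreads_from_calls(flat, sample = spec$source,
                              lambda_contigs = character())
  out$origin <- origin[match(out$read_id, sprintf("read%06d", seq_len(n_reads)))]
  if (n_lambda > 0) {
    lidx <- rep(seq_len(n_lambda), each = lambda_calls)
    lpos <- rep(cumsum(rgeom(lambda_calls, 1 / spec$spacing) + 1), n_lambda)
    lflat <- tibble::tibble(
      read_id = sprintf("lambda%04d", lidx),
      chrom = "lambda",
      pos = as.double(lpos),
      call = as.double(rbinom(n_lambda * lambda_calls, 1, spec$lambda_error))
    )
    lam <- longreads_from_calls(lflat, sample = spec$source,
                                lambda_contigs = "lambda")
    lam$origin <- "lambda"
    out <- dplyr::bind_rows(out, lam)
  }
  out
}

#' Generate an integer copy-number profile
#'
#' Tiles each chromosome with fixed-size bins at copy number 2, then
#' overwrites bins whose midpoint falls inside a planted segment.
#'
#' @param genome Tibble `chrom`, `length`.
#' @param bin_size Bin width, bp (terminal bins may be shorter).
#' @param segments Optional tibble `chrom`, `start`, `end`, `cn`.
#' @param cell Cell label.
#' @return A tibble `cell`, `chrom`, `start`, `end`, `cn`.
#' @export
generate_copy_number <- function(genome, bin_size = 5e6, segments = NULL,
                                 cell = "cell1") {
  bins <- dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    s <- seq(0, genome$length[i] - 1, by = bin_size)
    tibble::tibble(cell = cell, chrom = genome$chrom[i], start = s,
                   end = pmin(s + bin_size, genome$length[i]), cn = 2)
  }))
  if (!is.null(segments) && nrow(segments) > 0) {
    mid <- (bins$start + bins$end) / 2
    for (i in seq_len(nrow(segments))) {
      hit <- bins$chrom == segments$chrom[i] &
        mid >= segments$start[i] & mid < segments$end[i]
      bins$cn[hit] <- segments$cn[i]
    }
  }
  bins
}

#' Generate a synthetic beta-value probe matrix
#'
#' Probes are scattered uniformly over the genome; all samples draw betas
#' from a high-methylation background, and tumor samples additionally draw
#' from a hypomethylated distribution at probes inside `hypo_intervals`.
#'
#' @param spec A [synth_spec()] (genome and seed are used).
#' @param n_probes Number of probes.
#' @param n_tumor,n_normal Samples per group.
#' @param hypo_intervals Intervals hypomethylated in tumors.
#' @param background,hypo Beta shape pairs for the two states.
#' @return A list: `probes` (tibble `probe`, `chrom`, `pos`), `beta`
#'   (probes x samples matrix), `groups` (named vector of
#'   `"tumor"`/`"normal"`).
#' @export
generate_beta_matrix <- function(spec, n_probes = 5000, n_tumor = 6,
                                 n_normal = 6, hypo_intervals = NULL,
                                 background = c(8, 2), hypo = c(2, 6)) {
  withr::local_seed(spec$seed)
  ch <- sample(spec$genome$chrom, n_probes, replace = TRUE,
               prob = spec$genome$length / sum(spec$genome$length))
  len <- setNames(spec$genome$length, spec$genome$chrom)
  pos <- floor(runif(n_probes) * (len[ch] - 1)) + 1
  ord <- order(match(ch, spec$genome$chrom), pos)
  probes <- tibble::tibble(probe = sprintf("cg%06d", seq_len(n_probes)),
                           chrom = ch[ord], pos = pos[ord])
  samples <- c(sprintf("tumor%02d", seq_len(n_tumor)),
               sprintf("normal%02d", seq_len(n_normal)))
  groups <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
  beta <- matrix(rbeta(n_probes * length(samples), background[1], background[2]),
                 nrow = n_probes, dimnames = list(probes$probe, samples))
  if (!is.null(hypo_intervals) && nrow(hypo_intervals) > 0) {
    in_hypo <- positions_in_intervals(probes$chrom, probes$pos, hypo_intervals)
    tum <- which(groups == "tumor")
    beta[in_hypo, tum] <- rbeta(sum(in_hypo) * length(tum), hypo[1], hypo[2])
  }
  list(probes = probes, beta = beta, groups = groups)
}

#' Generate a group-structured expression matrix
#'
#' Per-gene lognormal expression with a multiplicative tumor effect on a
#' chosen subset of genes; the planted truth is returned for recovery tests.
#'
#' @param spec A [synth_spec()] (seed is used).
#' @param n_genes Number of genes.
#' @param n_tumor,n_normal Samples per group.
#' @param frac_down Fraction of genes downregulated in tumors.
#' @param fold Fold change applied to downregulated genes.
#' @param sdlog Lognormal within-group sd (log scale).
#' @param meanlog Lognormal mean (log scale) of baseline expression.
#' @return A list: `expr` (genes x samples matrix), `groups`, `truth`
#'   (tibble `gene`, `down`).
#' @export
generate_expression <- function(spec, n_genes = 500, n_tumor = 20,
                                n_normal = 20, frac_down = 0.1, fold = 2,
                                sdlog = 0.3, meanlog = log(10)) {
  withr::local_seed(spec$seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- c(sprintf("tumor%02d", seq_len(n_tumor)),
               sprintf("normal%02d", seq_len(n_normal)))
  groups <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
  base <- rnorm(n_genes, meanlog, 0.5)
  down <- seq_len(n_genes) <= round(frac_down * n_genes)
  mu <- matrix(base, n_genes, length(samples))
  mu[down, groups == "tumor"] <- mu[down, groups == "tumor"] - log(fold)
  expr <- matrix(rlnorm(length(mu), as.vector(mu), sdlog),
                 n_genes, length(samples), dimnames = list(genes, samples))
  list(expr = expr, groups = groups,
       truth = tibble::tibble(gene = genes, down = down))
}
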