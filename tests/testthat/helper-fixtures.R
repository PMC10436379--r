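# Shared fixtures, built once per session and cached. Seeds are fixed so
# every run sees the same synthetic data.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Unimodal normal methylome + track + threshold.
fx_normal <- function() fixture("normal", function() {
  sim <- generate_methylome(synth_normal_spec(seed = 101))
  track <- build_window_track(sim$calls, sim$layout)
  thr <- select_threshold(track)
  list(sim = sim, track = track, thr = thr)
})

# Bimodal tumor methylome (30% planted PMD) + track + threshold + PMDs.
fx_tumor <- function() fixture("tumor", function() {
  sim <- generate_methylome(synth_tumor_spec(seed = 202))
  track <- build_window_track(sim$calls, sim$layout)
  thr <- select_threshold(track)
  pmds <- call_pmds_per_source(track, thr)
  list(sim = sim, track = track, thr = thr, pmds = pmds)
})

# Tumor methylome with a nested 2-Mb PMI.
fx_pmi <- function() fixture("pmi", function() {
  sim <- generate_methylome(synth_tumor_spec(seed = 303, with_pmi = TRUE))
  track <- build_window_track(sim$calls, sim$layout)
  thr <- select_threshold(track)
  pmds <- call_pmds_per_source(track, thr)
  pmis <- call_pmis_per_source(pmds)
  list(sim = sim, track = track, thr = thr, pmds = pmds, pmis = pmis)
})

# Labelled spike-in reads at ~5 and ~30 CpGs/read over the tumor PMDs.
fx_spikein <- function() fixture("spikein", function() {
  sp <- synth_tumor_spec(seed = 404)
  pmds <- sp$true_pmds
  pmds$meth <- 0.30
  layout <- fx_normal()$sim$layout
  strata <- list(`5` = 5L, `30` = 30L)
  reads <- dplyr::bind_rows(lapply(names(strata), function(nm) {
    sp_i <- synth_tumor_spec(seed = 404 + strata[[nm]])
    r <- generate_longreads(sp_i, pmds, n_reads = 8000,
                            tumor_fraction = 0.01,
                            cpgs_per_read = strata[[nm]])
    r$stratum <- nm
    r$read_id <- paste0(nm, "_", r$read_id)
    r
  }))
  list(reads = reads, pmds = pmds, layout = layout)
})

# A tiny layout for deterministic unit tests: one 1-Mb chromosome,
# no CGIs or gaps unless supplied.
toy_layout <- function(len = 1e6, cgi = NULL, gaps = NULL) {
  genome_layout(tibble::tibble(chrom = "chr1", length = len),
                cgi = cgi, gaps = gaps)
}

# Hand-built window track: one source, contiguous window starts.
toy_track <- function(starts, meth, source = "s1", chrom = "chr1",
                      width = 1e5, n_cpg = 100) {
  tibble::tibble(source = source, chrom = chrom, start = starts,
                 end = starts + width, meth = meth, n_cpg = n_cpg)
}

# Threshold rows without running density estimation.
toy_threshold <- function(threshold, source = "s1") {
  out <- tibble::tibble(source = source, modality = "bimodal",
                        threshold = threshold, mode_lo = 0.2, mode_hi = 0.8,
                        n_windows = 1000L)
  class(out) <- c("pmd_threshold", class(out))
  out
}

# Construct a read tibble from explicit calls.
toy_read <- function(read_id, chrom, pos, call, sample = "s",
                     is_lambda = FALSE) {
  tibble::tibble(read_id = read_id, sample = sample, chrom = chrom,
                 start = min(pos) - 1, end = max(pos),
                 is_lambda = is_lambda,
                 calls = list(tibble::tibble(pos = as.double(pos),
                                             call = as.double(call))))
}

# Brute-force bp membership of an interval set at 1-kb resolution:
# returns a logical vector over the probed grid points.
bp_membership <- function(intervals, len = 1e7, chroms = c("chr1", "chr2"),
                          res = 1000) {
  unlist(lapply(chroms, function(ch) {
    probes <- seq(res / 2, len, by = res)  # 1-based probe positions
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) return(rep(FALSE, length(probes)))
    vapply(probes, function(p) any(iv$start < p & p <= iv$end), logical(1))
  }))
}

# Independent quantile normalization oracle (no ties expected).
qn_oracle <- function(M) {
  sorted <- apply(M, 2, sort)
  target <- rowMeans(sorted)
  out <- M
  for (j in seq_len(ncol(M))) out[, j] <- target[rank(M[, j])]
  out
}
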