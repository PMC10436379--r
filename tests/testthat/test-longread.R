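pmd1 <- tibble::tibble(chrom = "chr1", start = 1e5, end = 9e5)

test_that("per-read methylation uses only PMD, non-CGI calls", {
  cgi <- tibble::tibble(chrom = "chr1", start = 5e5, end = 5.1e5)
  lay <- toy_layout(cgi = cgi)
  # 40 eligible unmethylated calls
  r1 <- toy_read("r1", "chr1", seq(2e5, 2e5 + 39 * 100, 100), rep(0, 40))
  out <- read_methylation(r1, pmd1, lay)
  expect_equal(out$n_eligible, 40)
  expect_equal(out$mean_meth, 0)
  # calls only inside the CGI: nothing eligible
  r2 <- toy_read("r2", "chr1", seq(5.001e5, 5.09e5, 1000), 1)
  out2 <- read_methylation(r2, pmd1, lay)
  expect_equal(out2$n_eligible, 0)
  expect_true(is.na(out2$mean_meth))
  # calls outside the PMD: nothing eligible
  r3 <- toy_read("r3", "chr1", seq(9.2e5, 9.5e5, 1e4), 1)
  expect_equal(read_methylation(r3, pmd1, lay)$n_eligible, 0)
})

test_that("per-read stats match a brute-force membership oracle", {
  withr::local_seed(61)
  cgi <- tibble::tibble(chrom = "chr1", start = c(2e5, 6e5),
                        end = c(2.2e5, 6.1e5))
  lay <- toy_layout(cgi = cgi)
  pmds <- tibble::tibble(chrom = "chr1", start = c(1e5, 5e5),
                         end = c(3e5, 8e5))
  pos <- sort(sample.int(1e6, 200))
  call <- sample(0:1, 200, TRUE)
  r <- toy_read("rx", "chr1", pos, call)
  out <- read_methylation(r, pmds, lay)
  elig <- vapply(pos, function(p) {
    in_pmd <- any(pmds$start < p & p <= pmds$end)
    in_cgi <- any(cgi$start < p & p <= cgi$end)
    in_pmd && !in_cgi
  }, logical(1))
  expect_equal(out$n_eligible, sum(elig))
  expect_equal(out$mean_meth, mean(call[elig]))
})

test_that("the 30-CpG filter and 0.5 hypomethylation cut are enforced", {
  lay <- toy_layout()
  r29 <- toy_read("r29", "chr1", seq(2e5, by = 100, length.out = 29), 0)
  r30 <- toy_read("r30", "chr1", seq(2e5, by = 100, length.out = 30), 0)
  hi <- toy_read("hi", "chr1", seq(2e5, by = 100, length.out = 40),
                 rep(c(1, 1, 1, 1, 0), 8))   # mean 0.8
  lo <- toy_read("lo", "chr1", seq(2e5, by = 100, length.out = 40),
                 rep(c(1, 0, 0, 0, 0), 8))   # mean 0.2
  reads <- dplyr::bind_rows(r29, r30, hi, lo)
  out <- filter_and_classify(reads, pmd1, lay)
  expect_equal(out$passes, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$hypo, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("classification is monotone in the read threshold", {
  fx <- fx_spikein()
  cfg_lo <- pmd_config(read_hypo_threshold = 0.3)
  cfg_hi <- pmd_config(read_hypo_threshold = 0.6)
  n_lo <- sum(filter_and_classify(fx$reads, fx$pmds, fx$layout, cfg_lo)$hypo)
  n_hi <- sum(filter_and_classify(fx$reads, fx$pmds, fx$layout, cfg_hi)$hypo)
  expect_lte(n_lo, n_hi)
})

test_that("sample signal applies lambda and read-count QC", {
  lay <- toy_layout()
  mk_reads <- function(n, mean_meth, lambda_frac = 0, n_lambda = 2) {
    genomic <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      calls <- rep(c(1, 0), round(c(mean_meth, 1 - mean_meth) * 40))
      toy_read(sprintf("g%04d", i), "chr1",
               seq(2e5, by = 100, length.out = length(calls)), calls)
    }))
    lam <- dplyr::bind_rows(lapply(seq_len(n_lambda), function(i) {
      calls <- rep(c(1, 0), round(c(lambda_frac, 1 - lambda_frac) * 500))
      toy_read(sprintf("l%02d", i), "lambda", seq_along(calls), calls,
               is_lambda = TRUE)
    }))
    dplyr::bind_rows(genomic, lam)
  }
  # 2% lambda methylation fails QC
  bad_lambda <- mk_reads(350, 0.8, lambda_frac = 0.02)
  s1 <- sample_signal(bad_lambda, "metastatic", pmd1, lay)
  expect_false(s1$qc_pass)
  expect_true(is.na(s1$signal))
  # 250 PMD reads fail the metastatic minimum of 300
  few <- mk_reads(250, 0.8, lambda_frac = 0)
  expect_false(sample_signal(few, "metastatic", pmd1, lay)$qc_pass)
  # but pass the healthy minimum applied to a localized cohort needs 400
  expect_false(sample_signal(mk_reads(350, 0.8), "localized", pmd1, lay)$qc_pass)
  expect_true(sample_signal(mk_reads(450, 0.8), "localized", pmd1, lay)$qc_pass)
})

test_that("signal is the hypomethylated percentage of passing reads", {
  lay <- toy_layout()
  lo <- dplyr::bind_rows(lapply(1:50, function(i) {
    toy_read(sprintf("lo%04d", i), "chr1",
             seq(2e5, by = 100, length.out = 40), rep(0, 40))
  }))
  hi <- dplyr::bind_rows(lapply(1:950, function(i) {
    toy_read(sprintf("hi%04d", i), "chr1",
             seq(2e5, by = 100, length.out = 40), rep(1, 40))
  }))
  lam <- toy_read("l1", "lambda", 1:500, rep(0, 500), is_lambda = TRUE)
  s <- sample_signal(dplyr::bind_rows(lo, hi, lam), "metastatic", pmd1, lay)
  expect_true(s$qc_pass)
  expect_equal(s$n_passing, 1000)
  expect_equal(s$signal, 5.0)
  # duplication invariance: doubling every read leaves the signal unchanged
  dup <- dplyr::bind_rows(lo, hi, lo, hi, lam)
  dup$read_id <- make.unique(dup$read_id)
  expect_equal(sample_signal(dup, "metastatic", pmd1, lay)$signal, 5.0)
})

test_that("cohort comparison reproduces the closed-form t-test", {
  mk_sig <- function(cohort, values) {
    tibble::tibble(sample = paste0(cohort, seq_along(values)),
                   cohort = cohort, n_reads_in_pmds = 1000L,
                   n_passing = 1000L, n_hypo = 0L, lambda_meth = 0,
                   qc_pass = TRUE, signal = values)
  }
  withr::local_seed(71)
  h <- mk_sig("healthy", rnorm(10, 0.2, 0.1))
  m <- mk_sig("metastatic", rnorm(10, 3, 1))
  res <- cohort_compare(dplyr::bind_rows(h, m))
  tt <- t.test(m$signal, h$signal, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)
  expect_equal(res$max_ref, max(h$signal))
  expect_equal(res$n_above_ref_max, sum(m$signal > max(h$signal)))
  # identical groups: t = 0, p = 1
  same <- dplyr::bind_rows(mk_sig("healthy", c(1, 2, 3)),
                           mk_sig("localized", c(1, 2, 3)))
  res2 <- cohort_compare(same)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("a planted cohort shift is detected in almost all replicates", {
  mk_sig <- function(cohort, values) {
    tibble::tibble(sample = paste0(cohort, seq_along(values)),
                   cohort = cohort, n_reads_in_pmds = 1000L,
                   n_passing = 1000L, n_hypo = 0L, lambda_meth = 0,
                   qc_pass = TRUE, signal = pmax(values, 0))
  }
  withr::local_seed(72)
  hits <- vapply(1:20, function(i) {
    s <- dplyr::bind_rows(mk_sig("healthy", rnorm(10, 0.2, 0.1)),
                          mk_sig("metastatic", rnorm(10, 3, 1)))
    cohort_compare(s)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("PR model: perfect separation gives area 1, mixtures stay sane", {
  lay <- toy_layout()
  tum <- dplyr::bind_rows(lapply(1:20, function(i) {
    toy_read(sprintf("t%02d", i), "chr1",
             seq(2e5, by = 100, length.out = 10), rep(0, 10))
  }))
  tum$origin <- "tumor"
  nor <- dplyr::bind_rows(lapply(1:180, function(i) {
    toy_read(sprintf("n%03d", i), "chr1",
             seq(2e5, by = 100, length.out = 10), rep(1, 10))
  }))
  nor$origin <- "normal"
  pr <- spikein_pr_model(dplyr::bind_rows(tum, nor), pmd1, lay)
  expect_equal(pr$auc$auc, 1)
  expect_error(spikein_pr_model(nor, pmd1, lay), "both tumor and normal")
})

test_that("PR area grows with CpGs per read on the 1% spike-in", {
  fx <- fx_spikein()
  pr <- spikein_pr_model(fx$reads, fx$pmds, fx$layout)
  auc <- setNames(pr$auc$auc, pr$auc$stratum)
  expect_gte(auc[["30"]], auc[["5"]])
  expect_gt(auc[["30"]], 0.5)
  td <- tidy(pr)
  expect_true(all(td$precision >= 0 & td$precision <= 1))
  expect_s3_class(autoplot(pr), "ggplot")
})

test_that("permuted labels collapse precision to the spike fraction", {
  fx <- fx_spikein()
  reads <- fx$reads[fx$reads$stratum == "30", ]
  withr::local_seed(73)
  reads$origin <- sample(reads$origin)
  pr <- spikein_pr_model(reads, fx$pmds, fx$layout)
  spike <- mean(reads$origin == "tumor")
  expect_lt(pr$auc$auc, 2.5 * spike)
  expect_gt(pr$auc$auc, spike / 2.5)
})

test_that("synthetic normal reads yield near-zero signal", {
  sp <- synth_tumor_spec(seed = 81)
  pmds <- sp$true_pmds
  pmds$meth <- 0.30
  lay <- fx_normal()$sim$layout
  reads <- generate_longreads(sp, pmds, n_reads = 600, tumor_fraction = 0,
                              cpgs_per_read = 40, n_lambda = 3)
  s <- sample_signal(reads, "metastatic", pmds, lay)
  expect_true(s$qc_pass)
  expect_lt(s$signal, 2.5)
})
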