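test_that("PMD segmentation merges runs and applies the 250-kb filter", {
  # a 300-kb hypomethylated run and a 150-kb run
  run1 <- seq(1e6, 1.2e6, by = 200)     # spans [1.0, 1.3] Mb
  run2 <- seq(2e6, 2.05e6, by = 200)    # spans [2.0, 2.15] Mb
  normal <- seq(3e6, 3.2e6, by = 200)
  tr <- toy_track(c(run1, run2, normal),
                  meth = c(rep(0.2, length(run1)), rep(0.2, length(run2)),
                           rep(0.8, length(normal))))
  pm <- call_pmds_per_source(tr, toy_threshold(0.6))
  expect_equal(nrow(pm), 1)
  expect_equal(pm$start, 1e6)
  expect_equal(pm$end, 1.3e6)

  # nothing below threshold -> empty set
  none <- call_pmds_per_source(toy_track(run1, meth = rep(0.9, length(run1))),
                               toy_threshold(0.6))
  expect_equal(nrow(none), 0)
})

test_that("book-ended hypomethylated windows merge into one domain", {
  # windows [0,1e5) and [1e5,2e5) and [2e5,3e5): 0-gap runs merge
  tr <- toy_track(c(0, 1e5, 2e5), meth = c(0.2, 0.2, 0.2))
  pm <- call_pmds_per_source(tr, toy_threshold(0.6))
  expect_equal(nrow(pm), 1)
  expect_equal(pm$end - pm$start, 3e5)
})

test_that("union of per-source domain sets merges overlaps", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, kind = "PMD")
  b <- tibble::tibble(chrom = "chr1", start = 5e5, end = 1.5e6, kind = "PMD")
  u <- union_domains(list(a, b))
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 0)
  expect_equal(u$end, 1.5e6)
  # idempotence
  expect_equal(union_domains(list(a, a))[, 1:3], a[, 1:3])
})

test_that("union matches bp-membership oracle; commutative and associative", {
  withr::local_seed(21)
  rand_set <- function(n) {
    s <- sort(sample.int(9.8e6, n))
    tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = s, end = s + sample.int(2e5, n))
  }
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i) rand_set(8))
    u <- union_domains(sets)
    member_u <- bp_membership(u)
    member_each <- Reduce(`|`, lapply(sets, bp_membership))
    expect_equal(member_u, member_each)
    # commutativity / associativity
    u2 <- union_domains(rev(sets))
    expect_equal(u[, 1:3], u2[, 1:3])
    u3 <- union_domains(list(union_domains(sets[1:2]), sets[[3]]))
    expect_equal(u[, 1:3], u3[, 1:3])
  }
})

test_that("PMI calling keeps only gaps strictly inside (30 kb, 3 Mb)", {
  pmds <- tibble::tibble(
    source = "s1", chrom = "chr1",
    start = c(0e6, 1.02e6, 2.12e6, 6.62e6),
    end   = c(1.00e6, 2.02e6, 3.12e6, 7.62e6)
  )
  # gaps: 20 kb, 100 kb, 3.5 Mb
  pmi <- call_pmis_per_source(pmds)
  expect_equal(nrow(pmi), 1)
  expect_equal(pmi$start, 2.02e6)
  expect_equal(pmi$end, 2.12e6)

  # single PMD: chromosome ends are not flanked
  single <- call_pmis_per_source(pmds[1, ])
  expect_equal(nrow(single), 0)

  # exact 30 kb and exact 3 Mb are rejected (strict bounds)
  exact <- tibble::tibble(
    source = "s1", chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0, 1.03e6, 0, 4e6), end = c(1e6, 2e6, 1e6, 5e6)
  )
  expect_equal(nrow(call_pmis_per_source(exact)), 0)
})

test_that("quantile normalization is identity on identical columns", {
  M <- matrix(rep(seq(0.05, 0.60, length.out = 20), 8), ncol = 8)
  res <- core_from_matrix(M)
  expect_equal(res$qn, M, ignore_attr = TRUE)
  expect_equal(res$core, rowMeans(M) < 0.25)
})

test_that("quantile normalization matches an independent oracle", {
  withr::local_seed(33)
  M <- matrix(runif(20 * 8), 20, 8)
  res <- core_from_matrix(M)
  expect_equal(res$qn, qn_oracle(M), ignore_attr = TRUE)
})

test_that("core PMDs respect the 25% cutoff on the normalized row means", {
  M <- matrix(rep(seq(0.05, 0.60, length.out = 20), 8), ncol = 8)
  res <- core_from_matrix(M, cutoff = 0.25)
  expect_true(all(res$qn_mean[res$core] < 0.25))
  expect_true(all(res$qn_mean[!res$core] >= 0.25))
  # a single high source can push a row over the cutoff
  M2 <- matrix(0.21, 4, 8)
  M2[2, 8] <- 0.90
  M2[3, ] <- 0.8; M2[4, ] <- 0.5   # spread so QN has distinct quantiles
  res2 <- core_from_matrix(M2)
  expect_true(res2$core[1])
  expect_false(res2$core[2])
  expect_gte(res2$qn_mean[2], 0.25)
})

test_that("full core-PMD designation pools calls and flags uncovered rows", {
  total <- tibble::tibble(chrom = "chr1", start = c(0, 2e5, 4e5),
                          end = c(1e5, 3e5, 5e5), kind = "PMD")
  mk <- function(src, meths) {
    tibble::tibble(cell = src, source = src, chrom = "chr1",
                   pos = c(seq(1e4, 9e4, 1e4), seq(2.1e5, 2.9e5, 1e4)),
                   meth = rep(meths, each = 9), total = 1)
  }
  calls <- dplyr::bind_rows(mk("s1", c(0, 1)), mk("s2", c(0, 1)))
  expect_message(core <- designate_core_pmds(total, calls), "uncovered")
  expect_equal(dim(core$meth), c(3, 2))
  expect_equal(core$meth[1, ], c(s1 = 0, s2 = 0))
  expect_equal(core$meth[2, ], c(s1 = 1, s2 = 1))
  expect_true(is.na(core$meth[3, 1]))
  expect_true(core$domains$core[1])
  expect_false(core$domains$core[2])
  expect_false(core$domains$core[3])  # uncovered -> ineligible
  td <- tidy(core)
  expect_equal(nrow(td), 6)
  expect_equal(glance(core)$n_core, 1)
})

test_that("core PMIs require overlap in every source", {
  mk <- function(src, start, end) {
    tibble::tibble(source = src, chrom = "chr1", start = start, end = end,
                   kind = "PMI")
  }
  # identical in all three sources -> core
  all3 <- dplyr::bind_rows(mk("a", 1e6, 1.2e6), mk("b", 1e6, 1.2e6),
                           mk("c", 1e6, 1.2e6))
  expect_true(designate_core_pmis(all3)$core)
  # absent from one source -> not core
  two <- dplyr::bind_rows(mk("a", 1e6, 1.2e6), mk("b", 1e6, 1.2e6))
  expect_false(designate_core_pmis(two, sources = c("a", "b", "c"))$core)
  # staggered with a shared 10-kb overlap -> core
  stag <- dplyr::bind_rows(mk("a", 1.00e6, 1.10e6), mk("b", 1.05e6, 1.15e6),
                           mk("c", 1.09e6, 1.20e6))
  res <- designate_core_pmis(stag)
  expect_equal(nrow(res), 1)
  expect_true(res$core)
})

test_that("hypomethylated fraction is the merged-bp ratio", {
  starts <- seq(0, by = 1e5, length.out = 10)    # book-ended windows
  tr <- toy_track(starts, meth = c(rep(0.2, 3), rep(0.8, 7)))
  hf <- hypomethylated_fraction(tr, toy_threshold(0.6))
  expect_equal(hf$percent, 30)
  all_hypo <- hypomethylated_fraction(
    toy_track(starts, meth = rep(0.1, 10)), toy_threshold(0.6))
  expect_equal(all_hypo$percent, 100)
  # missing windows drop out of numerator and denominator
  tr_na <- toy_track(starts, meth = c(rep(0.2, 3), rep(0.8, 5), NA, NA))
  hf_na <- hypomethylated_fraction(tr_na, toy_threshold(0.6))
  expect_equal(hf_na$percent, 100 * 3 / 8)
})

test_that("raising the threshold never shrinks the hypomethylated set", {
  tr <- fx_tumor()$track
  lo <- call_pmds_per_source(tr, toy_threshold(0.45, source = "tumor1"),
                             pmd_config(min_pmd_length = 1L))
  hi <- call_pmds_per_source(tr, toy_threshold(0.65, source = "tumor1"),
                             pmd_config(min_pmd_length = 1L))
  # every bp called at the low threshold is called at the high one
  expect_equal(interval_bp(intersect_intervals(lo, hi)), interval_bp(lo))
})

test_that("planted PMDs are recovered with high bp-Jaccard", {
  fx <- fx_tumor()
  truth <- fx$sim$truth[fx$sim$truth$kind == "PMD", ]
  expect_gte(interval_jaccard(fx$pmds, truth), 0.95)
  # every per-source PMD honours the length floor
  expect_true(all(fx$pmds$end - fx$pmds$start >= 250000))
})

test_that("planted PMIs are recovered and bounded", {
  fx <- fx_pmi()
  truth <- fx$sim$truth[fx$sim$truth$kind == "PMI", ]
  expect_gte(interval_jaccard(fx$pmis, truth), 0.90)
  len <- fx$pmis$end - fx$pmis$start
  expect_true(all(len > 30000 & len < 3000000))
})

test_that("core sets are subsets of total sets", {
  fx <- fx_pmi()
  total_pmi <- designate_core_pmis(fx$pmis)
  expect_true(all(bp_membership(total_pmi[total_pmi$core, ]) <=
                    bp_membership(total_pmi)))
  total_pmd <- union_domains(fx$pmds)
  core <- designate_core_pmds(total_pmd, fx$sim$calls)
  core_iv <- core$domains[core$domains$core, ]
  expect_true(all(bp_membership(core_iv) <= bp_membership(total_pmd)))
})

test_that("interval Jaccard handles empty and partial overlap", {
  a <- tibble::tibble(chrom = "c", start = 0, end = 100)
  b <- tibble::tibble(chrom = "c", start = 50, end = 150)
  expect_equal(interval_jaccard(a, b), 1 / 3)
  expect_equal(interval_jaccard(a, a), 1)
  expect_equal(interval_jaccard(a, a[0, ]), 0)
  expect_equal(interval_jaccard(a[0, ], a[0, ]), 1)
})
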