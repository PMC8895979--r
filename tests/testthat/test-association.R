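test_that("SNP filters apply coverage, minor-count and coverage-tail rules", {
  bi <- make_bi(d_major = c(10, 30, 22, 40), d_minor = c(4, 7, 8, 10),
                nd_major = c(15, 30, 30, 35), nd_minor = c(5, 7, 0, 9))
  out <- apply_snp_filters(bi, tail = 0)
  # D coverage 14 < 15 -> low_coverage
  expect_equal(out$filter_reason[1], "low_coverage")
  # minor counts 7 and 7: neither reaches 8 -> low_minor
  expect_equal(out$filter_reason[2], "low_minor")
  # minor 8 in D, 0 in ND: "greater than 7 in at least one group" -> retained
  expect_true(out$passed_filters[3])
  expect_true(out$passed_filters[4])

  # 100 passing sites with distinct coverages, tail 2%: exactly the top 2 go
  set.seed(1)
  big <- make_bi(d_major = 100 + sample(100), d_minor = rep(20, 100),
                 nd_major = rep(100, 100), nd_minor = rep(20, 100))
  out2 <- apply_snp_filters(big, tail = 0.02)
  expect_equal(sum(out2$filter_reason == "high_coverage_tail"), 2L)
  tot <- big$d_major + big$d_minor + big$nd_major + big$nd_minor
  expect_equal(sort(tot[out2$filter_reason == "high_coverage_tail"]),
               sort(tot)[99:100])
  expect_error(apply_snp_filters(bi, min_cov = -1), "nonnegative")
})

test_that("filters are monotone in their thresholds", {
  set.seed(7)
  bi <- make_bi(d_major = rpois(400, 60), d_minor = rpois(400, 8),
                nd_major = rpois(400, 60), nd_minor = rpois(400, 8))
  n_pass <- function(mc, mm) sum(apply_snp_filters(bi, min_cov = mc,
                                                   min_minor = mm,
                                                   tail = 0)$passed_filters)
  for (mc in c(10, 15, 25)) expect_gte(n_pass(mc, 8), n_pass(mc + 5, 8))
  for (mm in c(4, 8, 12)) expect_gte(n_pass(15, mm), n_pass(15, mm + 2))
})

test_that("chi-squared matches the closed form and the stats oracle", {
  expect_equal(chi_squared_test(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_squared_test(10, 10, 10, 10)$pvalue, 1)
  ct <- chi_squared_test(20, 10, 10, 20)
  expect_equal(ct$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(ct$statistic, 6.6667, tolerance = 1e-4)
  expect_equal(ct$pvalue, 9.82e-3, tolerance = 1e-3)
  ct2 <- chi_squared_test(30, 0, 15, 15)
  expect_equal(ct2$statistic, 20, tolerance = 1e-12)
  expect_equal(ct2$pvalue, 7.74e-6, tolerance = 1e-3)

  # oracle: stats::chisq.test without continuity correction
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi_squared_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$pvalue, ref$p.value, tolerance = 1e-10)
  }

  # invariance under row and column swaps
  expect_equal(chi_squared_test(20, 10, 10, 20)$statistic,
               chi_squared_test(10, 20, 20, 10)$statistic)
  expect_equal(chi_squared_test(20, 10, 10, 20)$statistic,
               chi_squared_test(10, 20, 20, 10)$statistic)
  # zero margin: degenerate, statistic 0, P 1, with a warning
  expect_warning(z <- chi_squared_test(10, 0, 20, 0), "degenerate")
  expect_equal(z$statistic, 0)
  expect_equal(z$pvalue, 1)
})

test_that("log odds ratio applies the Haldane-Anscombe correction to zero cells", {
  expect_equal(log_odds_ratio(10, 10, 10, 10), 0)
  expect_equal(log_odds_ratio(20, 0, 10, 10), log(41), tolerance = 1e-12)
  expect_equal(log_odds_ratio(20, 0, 10, 10), 3.7136, tolerance = 1e-4)
  # antisymmetry under row swap
  expect_equal(log_odds_ratio(10, 10, 20, 0), -log(41), tolerance = 1e-12)
  # no zero cell: correction not applied in conditional mode
  expect_equal(log_odds_ratio(20, 5, 10, 10), log(20 * 10 / (5 * 10)))
  # unconditional mode adds 0.5 everywhere
  expect_equal(log_odds_ratio(20, 5, 10, 10, conditional = FALSE),
               log(20.5 * 10.5 / (5.5 * 10.5)))
  expect_error(log_odds_ratio(0, 0, 0, 0), "all-zero")
  # antisymmetric under column swap, vectorized
  a <- c(12, 7); b <- c(3, 0); cc <- c(8, 8); d <- c(9, 4)
  expect_equal(log_odds_ratio(b, a, d, cc), -log_odds_ratio(a, b, cc, d))
})

test_that("effective sample size reflects the pooled isofemale design", {
  # 25 strains, 4 replicate pools, 4 founder haplotypes: ~72.7 chromosomes
  expect_equal(effective_chromosomes(25, 4, 4), 25 / (1 / 4 + 3 / 32),
               tolerance = 1e-12)
  # a pool of unrelated diploids sequenced once: 1/(2k) + nothing else
  expect_equal(effective_chromosomes(25, 1e9, 2), 50, tolerance = 1e-6)
  expect_equal(effective_sample_size(100, 100), 50)
  # adjustment shrinks the statistic toward calibration
  bi <- make_bi(70, 23, 23, 70)
  raw <- pool_gwas(bi, tail = 0)
  adj <- pool_gwas(bi, tail = 0, adjust = TRUE)
  expect_lt(adj$chi2[1], raw$chi2[1])
  expect_equal(adj$ln_or, raw$ln_or)  # effects reported on raw counts
})

test_that("candidate calling is strict and ranks effect sizes", {
  res <- data.frame(chrom = "2R", pos = 1:4, passed_filters = c(TRUE, TRUE, TRUE, FALSE),
                    pvalue = c(1e-13, 0.5e-13, 0.2, 1e-20),
                    ln_or = c(3, -4, 0.1, 9))
  cand <- call_candidates(res, threshold = 1e-13)
  # P exactly at the threshold is not a candidate; filtered-out sites never are
  expect_equal(cand$pos, 2L)
  expect_equal(attr(cand, "n_tested"), 3L)
  # |ln OR| = 4 is the largest of the 3 tested SNPs: top 1/3
  expect_equal(cand$lnor_top_pct, 100 / 3, tolerance = 1e-10)
  empty <- call_candidates(res[res$pos > 90, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("gene aggregation assigns SNPs to gene bodies and needs >= 2 hits", {
  gff <- withr::local_tempfile(lines = c(
    "##gff-version 3",
    "2R\tsynth\tgene\t100\t200\t.\t+\t.\tID=geneA",
    "2R\tsynth\tgene\t180\t300\t.\t-\t.\tID=geneB",
    "3L\tsynth\tgene\t100\t200\t.\t+\t.\tID=geneC"))
  cand <- data.frame(chrom = c("2R", "2R", "3L"), pos = c(150, 185, 150),
                     pvalue = c(1e-15, 1e-14, 1e-16))
  hits <- genes_with_multiple_candidates(cand, gff, min_snps = 2)
  # geneA contains 150 and 185; geneB only 185; geneC only 150
  expect_equal(hits$gene_id, "geneA")
  expect_equal(hits$n_snps, 2L)
  expect_equal(hits$min_pvalue, 1e-15)
  # a SNP in two overlapping genes counts for both (brute-force check)
  hits1 <- genes_with_multiple_candidates(cand, gff, min_snps = 1)
  genes <- read_gff_genes(gff)
  brute <- vapply(seq_len(nrow(genes)), function(i)
    sum(cand$chrom == genes$chrom[i] & cand$pos >= genes$start[i] &
          cand$pos <= genes$end[i]), 0L)
  expect_equal(sort(hits1$n_snps), sort(brute[brute >= 1]))
  expect_equal(nrow(hits1), 3L)

  badgff <- withr::local_tempfile(lines = c("##gff-version 3",
                                            "2R\tsynth\tgene\t100\t200"))
  expect_error(genes_with_multiple_candidates(cand, badgff), "line 2")
  bad2 <- withr::local_tempfile(lines = "2R\tsynth\tgene\t300\t200\t.\t+\t.\tID=x")
  expect_error(read_gff_genes(bad2), "line 1")
})
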