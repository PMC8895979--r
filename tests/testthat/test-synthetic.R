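test_that("config validation catches bad parameters", {
  expect_error(sim_config(n_strains = 0), "n_strains")
  expect_error(sim_config(error_rate = 0.3), "error_rate")
  expect_error(sim_config(maf_alpha = -1), "configuration error")
  expect_error(sim_config(n_causal = 2, effect_sizes = 1), "effect_sizes")
  expect_error(sim_config(n_sites = 1e9), "genome length")
})

test_that("identical config and seed give bit-identical outputs", {
  cfg <- sim_config(n_strains = 25, n_sites = 150, pool_strains = 3,
                    flies_per_strain = 4, seed = 1)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$sync$counts, b$sync$counts)
  # a different seed changes the draws
  c <- simulate_strains(sim_config(n_strains = 25, n_sites = 150,
                                   pool_strains = 3, flies_per_strain = 4,
                                   seed = 2))
  expect_false(identical(a$genotypes$dosages, c$dosages))
})

test_that("founder dosages follow the 4-haplotype binomial model", {
  # symmetric tight Beta around 0.5: mean dosage ~ 2 across many strains
  cfg <- sim_config(n_strains = 500, n_sites = 200, maf_alpha = 400,
                    maf_beta = 400, seed = 8)
  g <- simulate_strains(cfg)
  expect_true(all(g$dosages >= 0 & g$dosages <= 4))
  expect_equal(mean(g$dosages), 2, tolerance = 0.02)
  # population frequency 0 at a site -> every strain has dosage 0
  cfg0 <- sim_config(n_strains = 100, n_sites = 50, n_causal = 1,
                     effect_sizes = 0, causal_freq = 0, seed = 8)
  g0 <- simulate_strains(cfg0)
  expect_true(all(g0$dosages[, g0$sites$causal] == 0))
  # site catalog is sorted and matches the dosage columns
  expect_equal(nrow(g$sites), ncol(g$dosages))
  expect_true(!is.unsorted(order(g$sites$chrom, g$sites$pos)))
})

test_that("phenotype model reproduces forced dormancy rates and direction", {
  # no genetics, no strain effects, mu10 = logit(0.9): dormancy level ~ 0.9
  cfg <- sim_config(n_strains = 300, n_sites = 10, flies_per_strain = 13,
                    mu10 = qlogis(0.9), strain_sd = 0, seed = 12)
  ph <- simulate_phenotypes(simulate_strains(cfg), cfg)
  expect_equal(mean(ph$dormant[ph$temperature == "10C"]), 0.9, tolerance = 0.02)
  # mu10 > mu12: dormancy incidence higher at 10C than at 12C
  cfg2 <- sim_config(n_strains = 300, n_sites = 10, seed = 12)
  ph2 <- simulate_phenotypes(simulate_strains(cfg2), cfg2)
  expect_gt(mean(ph2$dormant[ph2$temperature == "10C"]),
            mean(ph2$dormant[ph2$temperature == "12C"]))
  # dormant flies lay no eggs; fewer eggs at 10C among producers
  expect_true(all(ph2$eggs[ph2$dormant] == 0))
  prod10 <- ph2$eggs[!ph2$dormant & ph2$temperature == "10C"]
  prod12 <- ph2$eggs[!ph2$dormant & ph2$temperature == "12C"]
  expect_lt(mean(prod10), mean(prod12))
})

test_that("default generator puts ~24% of phenotype variance between strains", {
  cfg <- sim_config(n_sites = 10, seed = 21)  # 562 strains x 13 flies
  ph <- simulate_phenotypes(simulate_strains(cfg), cfg)
  expect_lt(abs(variance_between_strains(ph, "10C") - 0.24), 0.05)
  expect_lt(abs(variance_between_strains(ph, "12C") - 0.24), 0.05)
})

test_that("pool counts conserve depth and respect the error model", {
  # error rate 0, all strains fixed for the reference base -> ref-only counts
  cfg <- sim_config(n_strains = 30, n_sites = 40, n_causal = 1,
                    effect_sizes = 0, causal_freq = 0, error_rate = 0,
                    pool_strains = 5, flies_per_strain = 4, seed = 14)
  g <- simulate_strains(cfg)
  pools <- generate_pool_counts(g, g$strains[1:5], g$strains[6:10], cfg)
  ci <- which(g$sites$causal)
  ref_col <- match(g$sites$ref[ci], c("A", "T", "C", "G"))
  for (lib in sync_libraries(pools$sync)) {
    cnt <- pools$sync$counts[ci, , lib]
    expect_equal(sum(cnt[-ref_col]), 0)
  }
  # with errors on, only the four nucleotide fields are ever populated
  cfg2 <- sim_config(n_strains = 30, n_sites = 40, pool_strains = 5,
                     flies_per_strain = 4, seed = 14)
  g2 <- simulate_strains(cfg2)
  p2 <- generate_pool_counts(g2, g2$strains[1:5], g2$strains[6:10], cfg2)
  expect_true(all(p2$sync$counts[, 5:6, ] == 0))
  # overlapping selections are a design error
  expect_error(generate_pool_counts(g2, g2$strains[1:5], g2$strains[5:9], cfg2),
               "overlap")
})

test_that("merged coverage matches the configured mean", {
  cfg <- sim_config(n_strains = 60, n_sites = 800, pool_strains = 10,
                    flies_per_strain = 6, seed = 19)
  st <- simulate_study(cfg)
  m <- merge_groups(st$sync, st$lib_groups)
  cov_d <- rowSums(m$counts[, , "D"])
  expect_equal(mean(cov_d), 93, tolerance = 0.02)
})

test_that("a planted causal SNP shifts pool frequencies in the effect direction", {
  diffs <- sapply(1:4, function(s) {
    cfg <- sim_config(n_strains = 200, n_sites = 60, n_causal = 1,
                      effect_sizes = 4, causal_freq = 0.5,
                      pool_strains = 20, flies_per_strain = 13, seed = 40 + s)
    tr <- simulate_study(cfg)$truth$causal
    tr$freq_D - tr$freq_ND
  })
  expect_true(all(diffs > 0))
  # monotonicity: a larger effect gives a larger expected frequency shift
  d_small <- mean(sapply(1:3, function(s) {
    cfg <- sim_config(n_strains = 200, n_sites = 60, n_causal = 1,
                      effect_sizes = 0.5, causal_freq = 0.5,
                      pool_strains = 20, flies_per_strain = 13, seed = 50 + s)
    tr <- simulate_study(cfg)$truth$causal
    tr$freq_D - tr$freq_ND
  }))
  expect_gt(mean(diffs), d_small)
})

test_that("copy-number regions scale carrier depth by the copy ratio", {
  cfg <- sim_config(n_strains = 20, n_sites = 200,
                    chrom_lengths = c(sv = 200), n_causal = 0,
                    pool_strains = 5, flies_per_strain = 4,
                    mean_coverage = 80, seed = 23)
  g <- simulate_strains(cfg)
  selD <- g$strains[1:5]; selND <- g$strains[6:10]
  cfg$cnv_regions <- list(list(chrom = "sv", start = 51, end = 120,
                               carriers = selD, copy_ratio = 2))
  pools <- generate_pool_counts(g, selD, selND, cfg)
  m <- merge_groups(pools$sync, pools$groups)
  inside <- m$pos >= 51 & m$pos <= 120
  covD <- rowSums(m$counts[, , "D"]); covND <- rowSums(m$counts[, , "ND"])
  expect_equal(mean(covD[inside]) / mean(covND[inside]), 2, tolerance = 0.1)
  expect_equal(mean(covD[!inside]) / mean(covND[!inside]), 1, tolerance = 0.1)
  expect_equal(nrow(pools$truth$cnv), 1L)
  expect_equal(pools$truth$cnv$n_carriers_D, 5L)
})

test_that("null P-values from the full pipeline are uniform away from the calling boundary", {
  cfg <- sim_config(n_sites = 25000, seed = 77)
  st <- simulate_study(cfg)
  res <- pool_gwas(merge_groups(st$sync, st$lib_groups), adjust = TRUE)
  r <- res[res$passed_filters, ]
  mfrac <- (r$d_minor + r$nd_minor) /
    (r$d_major + r$d_minor + r$nd_major + r$nd_minor)
  p <- r$pvalue[mfrac >= 0.15]
  expect_gt(length(p), 10000)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
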