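flies_row <- function(strain, temperature, dormant, eggs = 0) {
  data.frame(strain = strain, temperature = temperature,
             fly_id = seq_along(dormant), dormant = dormant, eggs = eggs)
}

test_that("dormancy levels are fractions of oogenesis-blocked flies", {
  f <- rbind(
    flies_row("s1", "10C", c(rep(TRUE, 9), rep(FALSE, 4)),
              c(rep(0, 9), 3, 5, 2, 4)),
    flies_row("s1", "12C", rep(TRUE, 13)),
    flies_row("s2", "10C", c(TRUE, TRUE, FALSE, FALSE), c(0, 0, 4, 6)),
    flies_row("s2", "12C", c(FALSE, FALSE), c(0, 7)))
  p <- compute_dormancy_levels(f)
  expect_equal(p$level_10[p$strain == "s1"], 9 / 13, tolerance = 1e-12)
  expect_equal(p$level_12[p$strain == "s1"], 1)
  expect_true(is.na(p$mean_eggs_12[p$strain == "s1"]))  # all dormant, no producers
  # eggs {0,0,4,6} with 2 dormant flies: only producers counted
  expect_equal(p$mean_eggs_10[p$strain == "s2"], 5)
  # a non-dormant fly without eggs is not a producer either
  expect_equal(p$mean_eggs_12[p$strain == "s2"], 7)
  expect_true(all(p$level_10 >= 0 & p$level_10 <= 1))
})

test_that("required_sample_size is the minimal n reaching the target power", {
  expect_identical(required_sample_size(0, 0.3), 0L)
  expect_equal(required_sample_size(0.8, 0.5), 3)
  expect_equal(required_sample_size(0.8, 0.12), 13)
  expect_error(required_sample_size(1, 0.5), "p")
  expect_error(required_sample_size(0.5, 0), "a")
  expect_error(required_sample_size(0.5, 1), "a")
  # brute-force oracle over a (p, a) grid: smallest n with 1-(1-a)^n >= p
  for (p in seq(0.05, 0.95, by = 0.15)) {
    for (a in seq(0.08, 0.94, by = 0.13)) {
      n <- required_sample_size(p, a)
      brute <- 0L
      while (1 - (1 - a)^brute < p) brute <- brute + 1L
      expect_equal(n, brute)
      expect_true(1 - (1 - a)^n >= p)
      expect_true(n == 0L || 1 - (1 - a)^(n - 1) < p)
    }
  }
})

test_that("temperature comparison is a paired signed-rank test", {
  # distinct positive differences: exact two-sided signed-rank P = 2/2^8
  prof <- data.frame(strain = paste0("s", 1:8),
                     level_10 = seq(0.2, 0.9, by = 0.1) + seq(0.04, 0.32, by = 0.04),
                     level_12 = seq(0.2, 0.9, by = 0.1),
                     mean_eggs_10 = 1:8, mean_eggs_12 = 1:8 + seq(1, 4.5, by = 0.5))
  out <- compare_temperatures(prof)
  expect_equal(out$levels$pvalue, 2 / 2^8, tolerance = 1e-12)
  expect_lt(out$levels$pvalue, 0.05)
  expect_equal(out$eggs$pvalue, 2 / 2^8, tolerance = 1e-12)
  # a constant shift (fully tied differences) still comes out significant
  shift <- prof; shift$level_10 <- shift$level_12 + 0.3
  expect_lt(compare_temperatures(shift)$levels$pvalue, 0.05)

  same <- prof; same$level_12 <- same$level_10
  expect_warning(out2 <- compare_temperatures(same), "zero")
  expect_equal(out2$levels$pvalue, 1)
  expect_error(compare_temperatures(prof[1:4, ]), "at least 6")
})

test_that("P-value of the temperature contrast drops with more strains", {
  pv <- vapply(c(8, 30), function(n) {
    cfg <- sim_config(n_strains = n, n_sites = 10, flies_per_strain = 13,
                      pool_strains = 2, seed = 31)
    ph <- simulate_phenotypes(simulate_strains(cfg), cfg)
    compare_temperatures(compute_dormancy_levels(ph))$levels$pvalue
  }, 0)
  expect_lt(pv[2], pv[1])
})

test_that("between-strain variance fraction behaves as a one-way ICC", {
  # all strains share one Bernoulli rate -> estimate ~ 0
  set.seed(4)
  f0 <- data.frame(strain = rep(sprintf("s%03d", 1:300), each = 13),
                   temperature = "10C",
                   dormant = rbinom(300 * 13, 1, 0.4), eggs = 0)
  expect_lt(variance_between_strains(f0, "10C"), 0.05)
  # strains fully fixed at 0 or 1 -> estimate 1
  f1 <- data.frame(strain = rep(c("a", "b", "c", "d"), each = 5),
                   temperature = "10C",
                   dormant = rep(c(0, 1, 0, 1), each = 5), eggs = 0)
  expect_equal(variance_between_strains(f1, "10C"), 1)
  expect_error(variance_between_strains(f1[f1$strain == "a", ], "10C"),
               "at least 2")
  # matches the aov mean squares (method-of-moments oracle) on unbalanced data
  set.seed(9)
  fu <- data.frame(strain = rep(sprintf("s%02d", 1:20), times = rep(c(5, 9), 10)),
                   temperature = "12C",
                   dormant = rbinom(140, 1, rep(runif(20), times = rep(c(5, 9), 10))),
                   eggs = 0)
  ms <- summary(aov(dormant ~ strain, data = fu))[[1]]$`Mean Sq`
  n_i <- table(fu$strain); N <- sum(n_i); k <- length(n_i)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sb <- (ms[1] - ms[2]) / n0
  expect_equal(variance_between_strains(fu, "12C"),
               max(0, sb / (sb + ms[2])), tolerance = 1e-10)
})

test_that("ICC estimator recovers the simulated variance fraction", {
  for (target in c(0.1, 0.25)) {
    sd <- strain_sd_for_icc(target, mu = 0)
    expect_equal(icc_binary_theory(0, sd), target, tolerance = 1e-5)
    cfg <- sim_config(n_strains = 400, n_sites = 10, flies_per_strain = 13,
                      mu10 = 0, strain_sd = sd, pool_strains = 5, seed = 17)
    ph <- simulate_phenotypes(simulate_strains(cfg), cfg)
    expect_lt(abs(variance_between_strains(ph, "10C") - target), 0.05)
  }
})

test_that("extreme groups are rank-selected, disjoint and order-invariant", {
  prof <- data.frame(strain = paste0("s", 1:4),
                     level_10 = c(0, .1, .9, 1), level_12 = c(0, .2, .95, 1))
  g <- select_extreme_groups(prof, k = 1)
  expect_equal(g$nondormant_strains, "s1")
  expect_equal(g$dormant_strains, "s4")

  # all strains identical: deterministic tie-break by strain id, still disjoint
  tied <- data.frame(strain = sprintf("s%02d", 1:10),
                     level_10 = 0.5, level_12 = 0.5)
  gt <- select_extreme_groups(tied, k = 3)
  expect_length(intersect(gt$dormant_strains, gt$nondormant_strains), 0)
  expect_equal(gt$nondormant_strains, c("s01", "s02", "s03"))
  expect_equal(gt$dormant_strains, c("s04", "s05", "s06"))

  # row order does not matter
  set.seed(2)
  prof2 <- data.frame(strain = sprintf("s%03d", 1:60),
                      level_10 = round(runif(60), 2),
                      level_12 = round(runif(60), 2))
  g1 <- select_extreme_groups(prof2, k = 10)
  g2 <- select_extreme_groups(prof2[sample(60), ], k = 10)
  expect_equal(g1$dormant_strains, g2$dormant_strains)
  expect_equal(g1$nondormant_strains, g2$nondormant_strains)

  expect_error(select_extreme_groups(prof, k = 3), "design error")
})

test_that("selection on 562 simulated strains returns 25 disjoint strains per group", {
  cfg <- sim_config(n_sites = 10, seed = 3)
  ph <- simulate_phenotypes(simulate_strains(cfg), cfg)
  g <- select_extreme_groups(compute_dormancy_levels(ph), k = 25)
  expect_length(g$dormant_strains, 25)
  expect_length(g$nondormant_strains, 25)
  expect_length(intersect(g$dormant_strains, g$nondormant_strains), 0)
  # selected tails are extreme on their defining temperature
  p <- compute_dormancy_levels(ph)
  expect_true(max(p$level_10[p$strain %in% g$nondormant_strains]) <=
                min(p$level_10[!(p$strain %in% g$nondormant_strains)]))
})
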