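# Strain-level dormancy phenotype analysis: dormancy levels, temperature
# comparison, variance partition, sample-size formula, extreme-group
# selection.

#' Summarize per-fly data into strain dormancy profiles
#'
#' The dormancy level of a strain at a temperature is the fraction of assayed
#' flies whose oogenesis was blocked (dormant). Mean egg counts are computed
#' over egg-producing flies only; strains where no fly produced eggs get NA.
#' A missing strain-temperature cell is reported as NA and excluded from
#' paired tests downstream.
#'
#' @param flies data.frame with columns strain, temperature ("10C"/"12C"),
#'   dormant (logical or 0/1), eggs.
#' @return a data.frame with one row per strain: strain, level_10, level_12,
#'   n_10, n_12, mean_eggs_10, mean_eggs_12.
#' @export
compute_dormancy_levels <- function(flies) {
  stopifnot(all(c("strain", "temperature", "dormant", "eggs") %in% names(flies)))
  dt <- data.table::as.data.table(flies)
  dt[, dormant := as.logical(dormant)]
  agg <- dt[, .(level = mean(dormant), n = .N,
                mean_eggs = if (any(eggs > 0)) mean(eggs[eggs > 0]) else NA_real_),
            by = .(strain, temperature)]
  wide <- data.table::dcast(agg, strain ~ temperature,
                            value.var = c("level", "n", "mean_eggs"))
  need <- c("level_10C", "level_12C", "n_10C", "n_12C", "mean_eggs_10C", "mean_eggs_12C")
  for (col in setdiff(need, names(wide))) wide[, (col) := NA_real_]
  out <- data.frame(strain = wide$strain,
                    level_10 = wide$level_10C, level_12 = wide$level_12C,
                    n_10 = wide$n_10C, n_12 = wide$n_12C,
                    mean_eggs_10 = wide$mean_eggs_10C,
                    mean_eggs_12 = wide$mean_eggs_12C)
  out[order(out$strain), , drop = FALSE]
}

#' Flies needed to detect the minor phenotype of a strain
#'
#' Smallest n with 1 - (1 - a)^n >= p: the number of flies that must be
#' assayed so that, with power at least p, at least one fly shows a phenotype
#' segregating at frequency a within the strain. Equivalently the ceiling of
#' log(1 - p) / log(1 - a).
#'
#' @param p minimum statistical power, in (0, 1); p = 0 returns 0.
#' @param a frequency of the minor phenotype, in (0, 1).
#' @return integer sample size.
#' @export
required_sample_size <- function(p, a) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p >= 1)
    stop("'p' must lie in [0, 1)", call. = FALSE)
  assert_prob(a, "a")
  if (p == 0) return(0L)
  reach <- function(n) 1 - (1 - a)^n
  n <- max(0L, as.integer(ceiling(log1p(-p) / log1p(-a))))
  while (n > 0L && reach(n - 1L) >= p) n <- n - 1L
  while (reach(n) < p) n <- n + 1L
  n
}

#' Compare dormancy and fecundity between the two temperature regimes
#'
#' Two independent Wilcoxon signed-rank tests on paired per-strain values:
#' one on dormancy levels, one on mean egg counts. Strains missing either
#' temperature (or either egg mean, for the egg test) are excluded; zero
#' differences are dropped (Wilcoxon's original rule, as `wilcox.test` does);
#' the exact distribution is used for up to 25 informative pairs and the
#' normal approximation beyond.
#'
#' @param profiles a profile data.frame from [compute_dormancy_levels()].
#' @return a list with components `levels` and `eggs`, each a list with
#'   statistic, pvalue and n (informative pairs).
#' @export
compare_temperatures <- function(profiles) {
  run_test <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 6L)
      stop("need at least 6 strains observed at both temperatures", call. = FALSE)
    d <- x - y
    n_inf <- sum(d != 0)
    if (n_inf == 0L) {
      warning("all paired differences are zero; degenerate test, P = 1")
      return(list(statistic = NA_real_, pvalue = 1, n = 0L))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = n_inf <= 25L))
    list(statistic = unname(wt$statistic), pvalue = wt$p.value, n = n_inf)
  }
  list(levels = run_test(profiles$level_10, profiles$level_12),
       eggs = run_test(profiles$mean_eggs_10, profiles$mean_eggs_12))
}

#' Between-strain fraction of phenotypic variance
#'
#' One-way random-effects intraclass correlation of the per-fly binary
#' dormancy outcome, estimated by method-of-moments ANOVA on the 0/1 scale
#' (no liability transform): sigma2_b = (MSB - MSW) / n0 with the standard
#' unbalanced-design n0, and ICC = sigma2_b / (sigma2_b + MSW). Negative
#' estimates are clamped to 0.
#'
#' @param flies per-fly data.frame (strain, temperature, dormant).
#' @param temperature which regime to analyze ("10C" or "12C").
#' @return the estimated ICC in [0, 1].
#' @export
variance_between_strains <- function(flies, temperature) {
  sub <- flies[flies$temperature == temperature, , drop = FALSE]
  y <- as.numeric(as.logical(sub$dormant))
  g <- factor(sub$strain)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 strains", call. = FALSE)
  N <- length(y)
  n_i <- tabulate(g)
  ybar_i <- tapply(y, g, mean)
  ybar <- mean(y)
  ssb <- sum(n_i * (ybar_i - ybar)^2)
  ssw <- sum((y - ybar_i[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sigma_b <- (msb - msw) / n0
  if (sigma_b <= 0) return(0)
  if (msw == 0) return(1)
  min(1, sigma_b / (sigma_b + msw))
}

#' Select the extreme Dormant and Non-Dormant strain groups
#'
#' The Non-Dormant group is the k strains with the lowest dormancy level at
#' 10 degrees C (nondormant there implies nondormant at both temperatures);
#' the Dormant group is the k strains with the highest level at 12 degrees C.
#' Ties are broken by the other temperature's level and then by strain id,
#' so selection is deterministic and invariant to row order. If the two
#' greedy sets overlap, a contested strain goes to the group where its rank
#' is more extreme and the other group takes the next strain in its ranking.
#' A centered (unscaled) 2-component PCA of the per-strain level pairs is
#' returned for reporting and plotting.
#'
#' @param profiles a profile data.frame from [compute_dormancy_levels()].
#' @param k strains per group.
#' @return a list of class `extreme_groups` with components dormant_strains,
#'   nondormant_strains (each length k, ordered by extremity) and
#'   pca_coordinates (strain, PC1, PC2, group).
#' @export
select_extreme_groups <- function(profiles, k) {
  assert_count(k, "k")
  elig <- profiles[!is.na(profiles$level_10) & !is.na(profiles$level_12), , drop = FALSE]
  if (nrow(elig) < 2L * k)
    stop(sprintf("design error: need at least %d strains with both temperatures, have %d",
                 2L * k, nrow(elig)), call. = FALSE)
  nd_ord <- order(elig$level_10, elig$level_12, elig$strain)
  d_ord <- order(-elig$level_12, -elig$level_10, elig$strain)
  rank_nd <- rank_d <- integer(nrow(elig))
  rank_nd[nd_ord] <- seq_len(nrow(elig))
  rank_d[d_ord] <- seq_len(nrow(elig))
  ND <- nd_ord[seq_len(k)]
  D <- d_ord[seq_len(k)]
  nd_ptr <- d_ptr <- k
  advance <- function(ordv, ptr, taken) {
    repeat {
      ptr <- ptr + 1L
      if (ptr > length(ordv))
        stop("design error: cannot form disjoint groups", call. = FALSE)
      if (!(ordv[ptr] %in% taken)) return(list(ptr = ptr, nxt = ordv[ptr]))
    }
  }
  repeat {
    ov <- intersect(ND, D)
    if (!length(ov)) break
    s <- ov[1]
    if (rank_nd[s] <= rank_d[s]) {
      D <- setdiff(D, s)
      adv <- advance(d_ord, d_ptr, c(ND, D))
      d_ptr <- adv$ptr; D <- c(D, adv$nxt)
    } else {
      ND <- setdiff(ND, s)
      adv <- advance(nd_ord, nd_ptr, c(ND, D))
      nd_ptr <- adv$ptr; ND <- c(ND, adv$nxt)
    }
  }
  ND <- ND[order(rank_nd[ND])]
  D <- D[order(rank_d[D])]
  pc <- stats::prcomp(cbind(elig$level_10, elig$level_12),
                      center = TRUE, scale. = FALSE)
  grp <- rep("other", nrow(elig))
  grp[ND] <- "ND"; grp[D] <- "D"
  structure(list(
    dormant_strains = elig$strain[D],
    nondormant_strains = elig$strain[ND],
    pca_coordinates = data.frame(strain = elig$strain,
                                 PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                                 group = grp)), class = "extreme_groups")
}
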