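# Label-permutation null distribution and empirical false discovery rate.
#
# The D/ND labels of the 2k replicate libraries are shuffled prior to
# merging; every distinct relabeling into two groups of k (a partition and
# its complement counted once, the original excluded) yields one null
# dataset, re-analyzed with the same filters and test as the observed run.

#' Enumerate label permutations of the replicate libraries
#'
#' All distinct unordered partitions of the libraries into two groups of
#' `group_size`, canonicalized so that group1 contains the lexicographically
#' smallest library id (a partition and its complement are the same null
#' dataset). The original D/ND partition, when supplied, is excluded. The
#' count is choose(2k, k)/2 - 1 with the original removed: 34 for 8
#' libraries in groups of 4.
#'
#' @param library_ids character vector of library ids.
#' @param group_size libraries per group (must be half of the total).
#' @param original optional character vector: the library ids of one side of
#'   the observed partition, to be excluded.
#' @return a list of partitions, each a list with `group1` and `group2`.
#' @export
enumerate_partitions <- function(library_ids, group_size, original = NULL) {
  assert_count(group_size, "group_size")
  if (length(library_ids) != 2L * group_size)
    stop("design error: need exactly 2 * group_size libraries", call. = FALSE)
  if (anyDuplicated(library_ids))
    stop("design error: duplicate library ids", call. = FALSE)
  anchor <- min(library_ids)
  cmb <- utils::combn(sort(library_ids), group_size, simplify = FALSE)
  cmb <- Filter(function(g) anchor %in% g, cmb)
  parts <- lapply(cmb, function(g)
    list(group1 = g, group2 = setdiff(sort(library_ids), g)))
  if (!is.null(original)) {
    key <- canonical_partition_key(original, library_ids)
    parts <- Filter(function(p) canonical_partition_key(p$group1, library_ids) != key,
                    parts)
  }
  parts
}

canonical_partition_key <- function(side, library_ids) {
  side <- sort(side)
  if (!(min(library_ids) %in% side)) side <- sort(setdiff(library_ids, side))
  paste(side, collapse = "|")
}

#' Re-run the association scan under permuted group labels
#'
#' For each partition the libraries are merged according to the permuted
#' labels and the association stage (biallelic extraction, SNP filters,
#' chi-squared test) is re-run with the same parameters as the observed
#' analysis. Per-partition SNP sets may differ after filtering; the null is
#' a collection of P-value vectors plus each partition's minimum.
#'
#' @param x the replicate-level `sync` object (all libraries).
#' @param partitions partition list from [enumerate_partitions()].
#' @param original character vector with one side of the observed partition;
#'   a partition equal to it raises an error.
#' @param ... association parameters passed to [pool_gwas()]
#'   (min_cov, min_minor, tail, adjust, n_chrom, ...).
#' @return a list of class `perm_null`: `pvalues` (list of numeric vectors)
#'   and `summary` (data.frame partition, n_snps, min_p).
#' @export
permutation_null <- function(x, partitions, original, ...) {
  stopifnot(inherits(x, "sync"))
  libs <- sync_libraries(x)
  key0 <- canonical_partition_key(original, libs)
  pvals <- vector("list", length(partitions))
  summ <- data.frame(partition = character(length(partitions)),
                     n_snps = integer(length(partitions)),
                     min_p = numeric(length(partitions)))
  for (i in seq_along(partitions)) {
    p <- partitions[[i]]
    if (!all(c(p$group1, p$group2) %in% libs) ||
        length(c(p$group1, p$group2)) != length(libs))
      stop("design error: partition does not match the sync libraries", call. = FALSE)
    if (canonical_partition_key(p$group1, libs) == key0)
      stop("design error: the original partition must be excluded from the null",
           call. = FALSE)
    g <- stats::setNames(ifelse(libs %in% p$group1, "D", "ND"), libs)
    res <- pool_gwas(merge_groups(x, g), ...)
    pv <- res$pvalue[res$passed_filters]
    pvals[[i]] <- pv
    summ$partition[i] <- paste(sort(p$group1), collapse = "+")
    summ$n_snps[i] <- length(pv)
    summ$min_p[i] <- if (length(pv)) min(pv) else NA_real_
  }
  structure(list(pvalues = pvals, summary = summ), class = "perm_null")
}

#' Simulate design-matched null P-value distributions
#'
#' Parametric null for the over-dispersion-aware FDR: at every biallelic
#' site, both groups are re-drawn from the pooled (combined D + ND) major
#' allele fraction through the full sampling chain of the pooled isofemale
#' design — k strain dosages from `haplotypes` founder haplotypes, 2
#' chromosomes per replicate fly drawn from each strain, and reads at the
#' observed per-group coverage — and the association stage (filters and
#' chi-squared test) is re-run. Unlike the label permutation (whose
#' pseudo-groups mix replicate pools that share strains, cancelling the
#' strain-sampling variance between the two disjoint strain sets), this null
#' reproduces the full dispersion of the observed statistic under no
#' association.
#'
#' @param bi unfiltered biallelic table from [extract_biallelic()].
#' @param n_datasets number of null datasets (default 34, matching the
#'   number of label permutations).
#' @param k_strains,n_replicates,haplotypes design of each pooled group.
#' @param seed integer seed.
#' @param min_cov,min_minor,tail,adjust,n_chrom association parameters, as in
#'   [pool_gwas()].
#' @return a list of class `perm_null`: `pvalues` (list of numeric vectors)
#'   and `summary` (data.frame partition, n_snps, min_p).
#' @export
simulate_null_pvalues <- function(bi, n_datasets = 34L, k_strains = 25L,
                                  n_replicates = 4L, haplotypes = 4L,
                                  seed = 1L, min_cov = 15L, min_minor = 8L,
                                  tail = 0.02, adjust = FALSE,
                                  n_chrom = effective_chromosomes(k_strains, n_replicates, haplotypes)) {
  assert_count(n_datasets, "n_datasets")
  n <- nrow(bi)
  if (!n) stop("empty biallelic table", call. = FALSE)
  cov_d <- bi$d_major + bi$d_minor
  cov_nd <- bi$nd_major + bi$nd_minor
  p0 <- (bi$d_major + bi$nd_major) / (cov_d + cov_nd)
  draw_group <- function(cov) {
    dos <- matrix(stats::rbinom(k_strains * n, haplotypes,
                                rep(p0, each = k_strains)), nrow = k_strains)
    chrom <- matrix(stats::rbinom(k_strains * n, 2L * n_replicates,
                                  as.vector(dos) / haplotypes),
                    nrow = k_strains)
    freq <- colSums(chrom) / (2 * n_replicates * k_strains)
    major <- stats::rbinom(n, cov, freq)
    list(major = major, minor = cov - major)
  }
  pvals <- vector("list", n_datasets)
  summ <- data.frame(partition = sprintf("sim%02d", seq_len(n_datasets)),
                     n_snps = integer(n_datasets), min_p = numeric(n_datasets))
  withr::with_seed(seed, {
    for (i in seq_len(n_datasets)) {
      gd <- draw_group(cov_d)
      gn <- draw_group(cov_nd)
      null_bi <- data.frame(chrom = bi$chrom, pos = bi$pos,
                            major = bi$major, minor = bi$minor,
                            d_major = gd$major, d_minor = gd$minor,
                            nd_major = gn$major, nd_minor = gn$minor)
      res <- pool_gwas(null_bi, min_cov = min_cov, min_minor = min_minor,
                       tail = tail, adjust = adjust, n_chrom = n_chrom)
      pv <- res$pvalue[res$passed_filters]
      pvals[[i]] <- pv
      summ$n_snps[i] <- length(pv)
      summ$min_p[i] <- if (length(pv)) min(pv) else NA_real_
    }
  })
  structure(list(pvalues = pvals, summary = summ), class = "perm_null")
}

#' Empirical false discovery rate from a null P-value distribution
#'
#' For each threshold t, q(t) is the mean number of null P-values <= t across
#' the null datasets, divided by the number of observed P-values <= t, capped
#' at 1. Thresholds with no observed discoveries give NA. Because the null
#' datasets inherit the full sampling structure of the observed data (label
#' permutation, or parametric resampling), this FDR accounts for the
#' overdispersion of pooled extreme groups.
#'
#' @param observed_p numeric vector of observed P-values.
#' @param null_p a `perm_null` object or list of numeric null P-value
#'   vectors.
#' @param thresholds P-value thresholds in (0, 1) at which to evaluate q.
#' @return a data.frame: threshold, n_observed, mean_null, q.
#' @export
empirical_fdr <- function(observed_p, null_p, thresholds = 10^seq(-15, -2, by = 1)) {
  if (!length(observed_p)) stop("empty observed P-value vector", call. = FALSE)
  if (inherits(null_p, "perm_null")) null_p <- null_p$pvalues
  if (!length(null_p)) stop("need at least one null P-value vector", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  thresholds <- sort(thresholds)
  obs <- sort(observed_p)
  nulls <- lapply(null_p, sort)
  n_obs <- findInterval(thresholds, obs)          # #{p_obs <= t}
  null_counts <- vapply(nulls, function(v) findInterval(thresholds, v),
                        numeric(length(thresholds)))
  if (is.null(dim(null_counts)))
    null_counts <- matrix(null_counts, nrow = length(thresholds))
  mean_null <- rowMeans(null_counts)
  q <- ifelse(n_obs > 0, pmin(1, mean_null / n_obs), NA_real_)
  data.frame(threshold = thresholds, n_observed = n_obs,
             mean_null = mean_null, q = q)
}

#' Smallest threshold controlling the empirical FDR
#'
#' @param fdr_table output of [empirical_fdr()].
#' @param alpha target FDR level.
#' @return the largest threshold with q <= alpha (the most generous cutoff
#'   still controlling the FDR), or NA if none.
#' @export
fdr_threshold <- function(fdr_table, alpha = 0.05) {
  ok <- which(!is.na(fdr_table$q) & fdr_table$q <= alpha)
  if (!length(ok)) return(NA_real_)
  max(fdr_table$threshold[ok])
}
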