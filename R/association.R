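# Allele-count association between the merged Dormant and Non-Dormant
# groups: SNP filters, chi-squared test, Haldane-Anscombe log odds ratios,
# candidate calling and gene-level aggregation.

#' Apply SNP calling filters to biallelic counts
#'
#' A site passes iff both groups have coverage (sum of the two allele
#' counts) of at least `min_cov` and the minor allele count reaches
#' `min_minor` in at least one group ("greater than 7" read strictly as
#' >= 8). Among the sites passing both, the `ceiling(tail * n)` sites with
#' the highest total (D + ND) coverage are removed, with ties broken by
#' (coverage, chrom, pos) so exactly that many go.
#'
#' @param bi biallelic count data.frame from [extract_biallelic()].
#' @param min_cov minimum per-group coverage (default 15).
#' @param min_minor minimum minor allele count in at least one group
#'   (default 8).
#' @param tail fraction of highest-coverage sites removed (default 0.02).
#' @return `bi` with logical column `passed_filters` and factor-like
#'   character column `filter_reason` (ok, low_coverage, low_minor,
#'   high_coverage_tail).
#' @export
apply_snp_filters <- function(bi, min_cov = 15L, min_minor = 8L, tail = 0.02) {
  if (min_cov < 0 || min_minor < 0 || tail < 0 || tail > 1)
    stop("filter thresholds must be nonnegative (tail in [0, 1])", call. = FALSE)
  n <- nrow(bi)
  cov_d <- bi$d_major + bi$d_minor
  cov_nd <- bi$nd_major + bi$nd_minor
  reason <- rep("ok", n)
  reason[!(bi$d_minor >= min_minor | bi$nd_minor >= min_minor)] <- "low_minor"
  reason[cov_d < min_cov | cov_nd < min_cov] <- "low_coverage"
  ok <- which(reason == "ok")
  m <- ceiling(tail * length(ok))
  if (m > 0L && length(ok)) {
    tot <- cov_d[ok] + cov_nd[ok]
    drop <- ok[order(-tot, bi$chrom[ok], bi$pos[ok])[seq_len(m)]]
    reason[drop] <- "high_coverage_tail"
  }
  bi$passed_filters <- reason == "ok"
  bi$filter_reason <- reason
  bi
}

#' Pearson chi-squared test on 2x2 allele count tables
#'
#' Standard (uncorrected) chi-squared statistic with 1 degree of freedom,
#' computed by the closed form N (ad - bc)^2 / (r1 r2 c1 c2), vectorized over
#' sites. Rows are groups (D, ND), columns alleles (major, minor). Tables
#' with a zero margin are degenerate: statistic 0, P-value 1, with a warning.
#'
#' @param a,b,c,d numeric vectors: d_major, d_minor, nd_major, nd_minor.
#'   Counts may be non-integer when rescaled to an effective sample size.
#' @return a list with numeric vectors `statistic` and `pvalue`.
#' @export
chi_squared_test <- function(a, b, c, d) {
  N <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den > 0, N * (a * d - b * c)^2 / den, 0)
  if (any(den <= 0 & N > 0))
    warning("degenerate 2x2 table(s) with a zero margin: statistic 0, P = 1")
  list(statistic = stat, pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Natural-log odds ratio with Haldane-Anscombe correction
#'
#' ln((a d) / (b c)) on the 2x2 table (a = d_major, b = d_minor,
#' c = nd_major, d = nd_minor). When any cell is zero and `ha_correction` is
#' TRUE, 0.5 is added to all four cells of that table before taking the ratio
#' (the correction is applied conditionally, only where needed to account for
#' zero counts; set `conditional = FALSE` to add 0.5 everywhere).
#'
#' @param a,b,c,d numeric count vectors.
#' @param ha_correction apply the Haldane-Anscombe correction (default TRUE).
#' @param conditional apply it only to tables with a zero cell (default TRUE).
#' @return numeric vector of natural-log odds ratios.
#' @export
log_odds_ratio <- function(a, b, c, d, ha_correction = TRUE, conditional = TRUE) {
  if (any(a + b + c + d == 0))
    stop("log odds ratio undefined for an all-zero table", call. = FALSE)
  if (ha_correction) {
    adj <- if (conditional) (a == 0 | b == 0 | c == 0 | d == 0) else TRUE
    a <- a + 0.5 * adj; b <- b + 0.5 * adj
    c <- c + 0.5 * adj; d <- d + 0.5 * adj
  }
  log((a * d) / (b * c))
}

#' Design-based effective chromosome number of a pooled extreme group
#'
#' A pool of k isofemale strains, sequenced as r replicate pools of one fly
#' each, does not carry 2 k r independent chromosomes: a strain segregates at
#' most h founder haplotypes (h = 4 for a single mated foundress), and the
#' replicate flies of a strain are related. The variance of the pool allele
#' frequency is p(1-p)/k * (1/h + (1 - 1/h)/(2r)), so the equivalent number
#' of independent chromosomes is k / (1/h + (1 - 1/h)/(2r)) — about 72.7 for
#' the default k = 25, r = 4, h = 4.
#'
#' @param k_strains strains per group.
#' @param n_replicates replicate pools per group (one fly per strain each).
#' @param haplotypes founder haplotypes per strain.
#' @return effective number of chromosomes.
#' @export
effective_chromosomes <- function(k_strains = 25L, n_replicates = 4L, haplotypes = 4L) {
  k_strains / (1 / haplotypes + (1 - 1 / haplotypes) / (2 * n_replicates))
}

#' Effective sample size of pooled read counts
#'
#' Combines the finite number of chromosomes in the pool with the read
#' sampling: n_eff = n_chrom * c / (n_chrom + c) for coverage c. Used by the
#' adjusted chi-squared test, which rescales each group's counts from c to
#' n_eff so the statistic is calibrated under the pooled design.
#'
#' @param n_chrom effective chromosomes in the pool
#'   (see [effective_chromosomes()]).
#' @param coverage read coverage (vectorized).
#' @return effective sample size(s).
#' @export
effective_sample_size <- function(n_chrom, coverage) {
  n_chrom * coverage / (n_chrom + coverage)
}

#' Genome-wide allele-frequency association scan
#'
#' Runs the association stage on a merged two-group sync object (or an
#' already-extracted biallelic table): biallelic extraction, SNP filters,
#' chi-squared test and Haldane-Anscombe log odds ratio for every passing
#' site. With `adjust = TRUE` the chi-squared test is computed on counts
#' rescaled to the effective sample size implied by `n_chrom` (the adjusted
#' chi-squared test, accounting for the overdispersion of pooled extreme
#' groups); the log odds ratio always uses the raw counts.
#'
#' @param x a merged `sync` object (libraries D, ND) or a biallelic
#'   data.frame from [extract_biallelic()].
#' @param min_cov,min_minor,tail filter settings, see [apply_snp_filters()].
#' @param adjust use the effective-sample-size rescaled statistic
#'   (default FALSE: the standard chi-squared test).
#' @param n_chrom effective chromosomes per group when `adjust = TRUE`.
#' @param ha_correction,conditional log odds ratio settings,
#'   see [log_odds_ratio()].
#' @return a data.frame with one row per biallelic site: chrom, pos, major,
#'   minor, the four counts, passed_filters, filter_reason, chi2, pvalue,
#'   ln_or (statistics NA for filtered sites).
#' @export
pool_gwas <- function(x, min_cov = 15L, min_minor = 8L, tail = 0.02,
                      adjust = FALSE, n_chrom = effective_chromosomes(),
                      ha_correction = TRUE, conditional = TRUE) {
  bi <- if (inherits(x, "sync")) extract_biallelic(x) else x
  res <- apply_snp_filters(bi, min_cov = min_cov, min_minor = min_minor, tail = tail)
  res$chi2 <- res$pvalue <- res$ln_or <- NA_real_
  p <- which(res$passed_filters)
  if (length(p)) {
    a <- res$d_major[p]; b <- res$d_minor[p]
    cc <- res$nd_major[p]; dd <- res$nd_minor[p]
    if (adjust) {
      cov_d <- a + b; cov_nd <- cc + dd
      sd_ <- effective_sample_size(n_chrom, cov_d) / cov_d
      snd <- effective_sample_size(n_chrom, cov_nd) / cov_nd
      ct <- chi_squared_test(a * sd_, b * sd_, cc * snd, dd * snd)
    } else {
      ct <- chi_squared_test(a, b, cc, dd)
    }
    res$chi2[p] <- ct$statistic
    res$pvalue[p] <- ct$pvalue
    res$ln_or[p] <- log_odds_ratio(a, b, cc, dd, ha_correction = ha_correction,
                                   conditional = conditional)
  }
  res
}

#' Call candidate SNPs below a P-value threshold
#'
#' Candidates are the filtered SNPs with P-value strictly below `threshold`.
#' For each candidate the percentile standing of its absolute log odds ratio
#' among all filtered SNPs is reported (`lnor_top_pct`: the percentage of
#' filtered SNPs with |ln OR| at least as large — small values mean the
#' candidate sits in the extreme tail of effect sizes).
#'
#' @param results association table from [pool_gwas()].
#' @param threshold candidate P-value threshold (default 1e-13, strict `<`).
#' @return the candidate subset of `results` with column `lnor_top_pct`,
#'   ordered by P-value; attribute `n_tested` holds the number of filtered
#'   SNPs.
#' @export
call_candidates <- function(results, threshold = 1e-13) {
  tested <- results[results$passed_filters, , drop = FALSE]
  cand <- tested[!is.na(tested$pvalue) & tested$pvalue < threshold, , drop = FALSE]
  if (nrow(cand)) {
    abs_all <- abs(tested$ln_or)
    cand$lnor_top_pct <- vapply(abs(cand$ln_or),
                                function(v) 100 * mean(abs_all >= v), 0)
    cand <- cand[order(cand$pvalue), , drop = FALSE]
  } else {
    cand$lnor_top_pct <- numeric(0)
  }
  attr(cand, "n_tested") <- nrow(tested)
  cand
}

#' Read gene features from a GFF3 file
#'
#' Minimal reader for gene-level aggregation: keeps rows whose type column is
#' "gene" and takes the gene id from the ID attribute. Lines that are not
#' comments and do not have nine tab-separated fields, or whose coordinates
#' are not valid (integer, start <= end), raise a format error naming the
#' line.
#'
#' @param path path to a GFF3 file.
#' @return a data.frame with columns gene_id, chrom, start, end (1-based,
#'   inclusive).
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop(sprintf("GFF3 format error at line %d: expected 9 tab-separated fields, found %d",
                 lineno[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop(sprintf("GFF3 format error at line %d: invalid coordinates '%s'..'%s'",
                 lineno[bad[1]], m[bad[1], 4], m[bad[1], 5]), call. = FALSE)
  g <- m[, 3] == "gene"
  id <- sub(".*ID=([^;]+).*", "\\1", m[g, 9])
  noid <- !grepl("ID=", m[g, 9])
  id[noid] <- sprintf("gene_line%d", lineno[g][noid])
  data.frame(gene_id = id, chrom = m[g, 1], start = start[g], end = end[g])
}

#' Genes carrying multiple candidate SNPs
#'
#' Assigns each candidate SNP to every gene whose body ([start, end],
#' 1-based inclusive, strand-agnostic, no flanking regions) contains its
#' position, and reports the genes with at least `min_snps` candidates,
#' sorted by their minimum P-value.
#'
#' @param candidates candidate table from [call_candidates()] (needs chrom,
#'   pos, pvalue).
#' @param genes a gene data.frame from [read_gff_genes()] or a path to a
#'   GFF3 file.
#' @param min_snps minimum candidate SNPs per gene (default 2).
#' @return a data.frame: gene_id, chrom, start, end, n_snps, min_pvalue,
#'   positions (comma-separated).
#' @export
genes_with_multiple_candidates <- function(candidates, genes, min_snps = 2L) {
  if (is.character(genes)) genes <- read_gff_genes(genes)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_snps = integer(),
                      min_pvalue = numeric(), positions = character())
  if (!nrow(candidates) || !nrow(genes)) return(empty)
  snp_gr <- GenomicRanges::GRanges(candidates$chrom,
                                   IRanges::IRanges(candidates$pos, candidates$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (!length(hits)) return(empty)
  dt <- data.table::data.table(
    gene = S4Vectors::subjectHits(hits),
    pos = candidates$pos[S4Vectors::queryHits(hits)],
    pvalue = candidates$pvalue[S4Vectors::queryHits(hits)])
  agg <- dt[, .(n_snps = .N, min_pvalue = min(pvalue),
                positions = paste(sort(unique(pos)), collapse = ",")), by = gene]
  agg <- agg[agg$n_snps >= min_snps, ]
  if (!nrow(agg)) return(empty)
  out <- data.frame(gene_id = genes$gene_id[agg$gene],
                    chrom = genes$chrom[agg$gene],
                    start = genes$start[agg$gene], end = genes$end[agg$gene],
                    n_snps = agg$n_snps, min_pvalue = agg$min_pvalue,
                    positions = agg$positions)
  out[order(out$min_pvalue), , drop = FALSE]
}
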