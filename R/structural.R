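# Coverage-window screen for structural polymorphisms: windows of divergent
# coverage between the merged groups, co-occurrence with significant SNPs,
# and a single-individual verification rule.
#
# This stage runs on sync data processed WITHOUT repeat masking and WITHOUT
# the high-coverage filter, since collapsed duplications are exactly the
# high-coverage repeats those filters remove. Depth here is total depth (all
# six count fields), unlike the association filters which use allele counts.

#' Mean coverage of non-overlapping genomic windows
#'
#' Tiles each chromosome from position 1 in `window`-bp tiles (0-based,
#' half-open; a trailing partial tile covers the chromosome end) and computes
#' the mean per-position total depth of each group in every tile. Positions
#' absent from the sync data contribute zero depth. Optionally counts the
#' significant SNPs falling in each window.
#'
#' @param x a merged `sync` object (libraries D, ND).
#' @param window window size in bp (default 200).
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   largest observed position per chromosome.
#' @param sig_positions optional data.frame (chrom, pos) of significant SNPs
#'   (e.g. candidates from the unfiltered-coverage association run).
#' @return a data.frame: chrom, start, end (0-based half-open), mean_cov_D,
#'   mean_cov_ND, diff (D - ND), n_sig_snps.
#' @export
window_coverage <- function(x, window = 200L, chrom_lengths = NULL,
                            sig_positions = NULL) {
  stopifnot(inherits(x, "sync"))
  if (!is.numeric(window) || window <= 0)
    stop("'window' must be a positive integer", call. = FALSE)
  window <- as.integer(window)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(x$pos, x$chrom, max)
  depth_d <- rowSums(x$counts[, , "D", drop = FALSE], dims = 1L)
  depth_nd <- rowSums(x$counts[, , "ND", drop = FALSE], dims = 1L)
  tiles <- do.call(rbind, lapply(names(chrom_lengths), function(cn) {
    len <- as.integer(chrom_lengths[[cn]])
    start <- seq.int(0L, len - 1L, by = window)
    data.frame(chrom = cn, start = start, end = pmin(start + window, len))
  }))
  site_tile <- (x$pos - 1L) %/% window
  key_site <- paste(x$chrom, site_tile)
  key_tile <- paste(tiles$chrom, tiles$start %/% window)
  sum_d <- tapply(depth_d, key_site, sum)
  sum_nd <- tapply(depth_nd, key_site, sum)
  width <- tiles$end - tiles$start
  lookup <- function(sums) {
    v <- as.vector(sums[key_tile])
    v[is.na(v)] <- 0
    v
  }
  tiles$mean_cov_D <- lookup(sum_d) / width
  tiles$mean_cov_ND <- lookup(sum_nd) / width
  tiles$diff <- tiles$mean_cov_D - tiles$mean_cov_ND
  tiles$n_sig_snps <- 0L
  if (!is.null(sig_positions) && nrow(sig_positions)) {
    key_sig <- paste(sig_positions$chrom, (sig_positions$pos - 1L) %/% window)
    cnt <- table(key_sig)
    hit <- key_tile %in% names(cnt)
    tiles$n_sig_snps[hit] <- as.integer(cnt[key_tile[hit]])
  }
  rownames(tiles) <- NULL
  tiles
}

#' Flag windows with divergent coverage between the groups
#'
#' A window is flagged when the absolute D - ND mean coverage difference
#' reaches `min_abs_diff` and (if `require_sig`) at least one significant
#' SNP falls inside it — the co-occurrence criterion of the structural
#' screen.
#'
#' @param windows window table from [window_coverage()].
#' @param min_abs_diff minimum absolute coverage difference (default 30).
#' @param require_sig require at least one significant SNP in the window
#'   (default TRUE).
#' @return the flagged subset of `windows`, ordered by |diff| decreasing.
#' @export
flag_divergent_windows <- function(windows, min_abs_diff = 30, require_sig = TRUE) {
  keep <- abs(windows$diff) >= min_abs_diff
  if (require_sig) keep <- keep & windows$n_sig_snps >= 1L
  out <- windows[keep, , drop = FALSE]
  out[order(-abs(out$diff)), , drop = FALSE]
}

#' Is a coverage signal driven by a single individual?
#'
#' Given per-individual mean depths over a candidate window (from
#' single-fly sequencing), classifies the signal: single_individual_driven
#' iff exactly one individual exceeds `ratio` times the median depth of all
#' individuals; shared iff two or more exceed it; inconclusive otherwise.
#' A pool-level coverage signal that one individual explains is a private
#' duplication, not a group-associated structural variant.
#'
#' @param depths numeric vector (optionally named) of per-individual mean
#'   depths; at least 3 individuals.
#' @param ratio multiple of the median that counts as high coverage
#'   (default 3).
#' @return a list with `verdict` ("single_individual_driven", "shared" or
#'   "inconclusive"), `individual` (name or index of the offender, NA unless
#'   single), `n_exceed` and `median_depth`.
#' @export
individual_heterogeneity <- function(depths, ratio = 3.0) {
  if (length(depths) < 3L)
    stop("need at least 3 individuals for the heterogeneity check", call. = FALSE)
  med <- stats::median(depths)
  exceed <- which(depths > ratio * med)
  verdict <- if (length(exceed) == 1L) "single_individual_driven"
             else if (length(exceed) >= 2L) "shared" else "inconclusive"
  offender <- if (length(exceed) == 1L) {
    if (!is.null(names(depths))) names(depths)[exceed] else exceed
  } else NA
  list(verdict = verdict, individual = offender,
       n_exceed = length(exceed), median_depth = med)
}
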