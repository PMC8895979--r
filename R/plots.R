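# Plotting helpers.

#' Manhattan plot of the association scan
#'
#' -log10 P-values along the genome, chromosomes alternating in color, with
#' a dashed line at the candidate threshold.
#'
#' @param results association table from [pool_gwas()].
#' @param threshold candidate P-value threshold drawn as a line
#'   (default 1e-13).
#' @return a ggplot object.
#' @export
plot_manhattan <- function(results, threshold = 1e-13) {
  df <- results[results$passed_filters & !is.na(results$pvalue), , drop = FALSE]
  chroms <- unique(df$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cn) max(df$pos[df$chrom == cn]), 0)))
  df$xpos <- df$pos + offs[match(df$chrom, chroms)]
  df$logp <- -log10(df$pvalue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xpos, y = .data$logp,
                                   color = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::scale_x_continuous(
      breaks = offs[-length(offs)] + diff(offs) / 2, labels = chroms) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
}

#' PCA plot of strain dormancy levels
#'
#' Scatter of the two principal components of the per-strain (level at 10C,
#' level at 12C) pairs, highlighting the selected extreme groups.
#'
#' @param groups an `extreme_groups` object from [select_extreme_groups()].
#' @return a ggplot object.
#' @export
plot_dormancy_pca <- function(groups) {
  df <- groups$pca_coordinates
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(D = "firebrick", ND = "steelblue",
                                           other = "grey70")) +
    ggplot2::labs(color = "group") +
    ggplot2::theme_minimal()
}
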