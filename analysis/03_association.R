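#!/usr/bin/env Rscript
# Step 3 — allele-count association scan.
#
# Repeat-masks the sync data, merges the 4 replicate libraries of each
# extreme group (replicate flies of a strain are related, so replicates are
# not independent), extracts biallelic counts, applies the SNP filters
# (coverage >= 15 per group, minor count >= 8 in at least one group, top 2%
# coverage removed) and tests every SNP. Two statistics are reported: the
# standard chi-squared test (used for the 1e-13 candidate threshold) and the
# effective-sample-size adjusted test, whose P-values are calibrated under
# the pooled isofemale design and feed the FDR in step 4. Candidate genes
# need at least 2 candidate SNPs in the gene body.

suppressMessages(library(dormgwas))

sim_dir <- "results/simdata"
out_dir <- "results/association"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sync <- read_sync(file.path(sim_dir, "pools.sync"),
                  libraries = c(paste0("D", 1:4), paste0("ND", 1:4)))
lib_groups <- read.csv(file.path(sim_dir, "lib_groups.csv"))
masked <- mask_sites(sync, file.path(sim_dir, "mask.bed"))
cat(sprintf("sites: %d total, %d after repeat/TE masking\n",
            n_sites(sync), n_sites(masked)))

merged <- merge_groups(masked, lib_groups)
res <- pool_gwas(merged)                 # standard chi-squared
res_adj <- pool_gwas(merged, adjust = TRUE)
res$pvalue_adj <- res_adj$pvalue
res$chi2_adj <- res_adj$chi2
cat(sprintf("biallelic sites: %d; SNPs passing filters: %d\n",
            nrow(res), sum(res$passed_filters)))
cat(sprintf("mean merged coverage per group: %.1f\n",
            mean(rowSums(merged$counts[, , "D"]))))

write.table(res, file.path(out_dir, "association.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cand <- call_candidates(res, threshold = 1e-13)
cat(sprintf("candidate SNPs at P < 1e-13 (standard test): %d of %d tested\n",
            nrow(cand), attr(cand, "n_tested")))
if (nrow(cand)) {
  truth <- read.csv(file.path(sim_dir, "truth_causal.csv"))
  cand$planted <- paste(cand$chrom, cand$pos) %in% paste(truth$chrom, truth$pos)
  print(cand[, c("chrom", "pos", "pvalue", "ln_or", "lnor_top_pct", "planted")],
        row.names = FALSE)
}
write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

genes <- genes_with_multiple_candidates(cand, file.path(sim_dir, "genes.gff3"),
                                        min_snps = 2)
cat(sprintf("genes with >= 2 candidate SNPs: %d\n", nrow(genes)))
write.table(genes, file.path(out_dir, "candidate_genes.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

ggplot2::ggsave(file.path(out_dir, "manhattan.png"),
                plot_manhattan(res, threshold = 1e-13),
                width = 9, height = 3.2, dpi = 150)
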