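#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Emulates the pooled-sequencing dormancy GWAS design: 562 isofemale strains
# phenotyped with 13 flies per strain at each of two dormancy-inducing
# temperatures (10 and 12 C), the 25 most extreme strains per phenotype tail
# sequenced as 4 replicate pools each, merged coverage ~93 per group. Five
# causal SNPs of decreasing liability effect are planted so the downstream
# association steps have a weak polygenic signal to chase, plus one
# copy-number region carried by a single dormant-pool strain for the
# structural screen.
#
# Writes sync, phenotype, mask, annotation and truth files under
# results/simdata/.

suppressMessages(library(dormgwas))

out_dir <- "results/simdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 42L

cfg <- sim_config(n_sites = 20000,
                  n_causal = 5, effect_sizes = c(6, 4, 3, 2, 1),
                  causal_freq = rep(0.5, 5), seed = seed)
st <- simulate_study(cfg)

pools <- generate_pool_counts(st$genotypes, st$groups$dormant_strains,
                              st$groups$nondormant_strains, cfg)

# The structural screen works on every-position coverage (the sync a real
# mpileup yields), so a 10-kb region is simulated at full density for the
# same extreme groups, with a private duplication: one dormant-pool strain
# carries a 200-bp segment at 30x copy number.
cfg_sv <- sim_config(n_sites = 10000, chrom_lengths = c(region = 10000),
                     seed = seed + 1L)
g_sv <- simulate_strains(cfg_sv)
cfg_sv$cnv_regions <- list(list(chrom = "region", start = 5001, end = 5200,
                                carriers = st$groups$dormant_strains[1],
                                copy_ratio = 30))
pools_sv <- generate_pool_counts(g_sv, st$groups$dormant_strains,
                                 st$groups$nondormant_strains, cfg_sv)
write_sync(pools_sv$sync, file.path(out_dir, "region.sync"))
write.csv(pools_sv$truth$cnv, file.path(out_dir, "truth_cnv.csv"),
          row.names = FALSE)

write_sync(pools$sync, file.path(out_dir, "pools.sync"))
write.csv(st$phenotypes, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
write.csv(data.frame(library = names(pools$groups), group = pools$groups),
          file.path(out_dir, "lib_groups.csv"), row.names = FALSE)
write.csv(pools$truth$causal, file.path(out_dir, "truth_causal.csv"),
          row.names = FALSE)
write_bed(synth_mask_bed(cfg$chrom_lengths, fraction = 0.05, seed = seed),
          file.path(out_dir, "mask.bed"))
synth_genes_gff(cfg$chrom_lengths, n_genes = 400, seed = seed,
                path = file.path(out_dir, "genes.gff3"))

cat(sprintf("simulated %d strains, %d sites, %d libraries\n",
            cfg$n_strains, n_sites(pools$sync), length(sync_libraries(pools$sync))))
cat(sprintf("planted causal SNPs (liability effects %s):\n",
            paste(cfg$effect_sizes, collapse = ", ")))
print(pools$truth$causal, row.names = FALSE)
cat("outputs in", out_dir, "\n")
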