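# Synthetic study generator: isofemale strains, two-temperature dormancy
# phenotypes, extreme-pool sequencing counts, optional planted causal SNPs
# and copy-number regions.
#
# The design emulated: several hundred isofemale strains founded each by a
# single mated female (hence at most 4 founder haplotypes per locus), scored
# for oogenesis arrest at two dormancy-inducing temperatures, with the 25 most
# extreme strains per phenotype tail sequenced as 4 replicate pools of one fly
# per strain, merged to a mean coverage of ~93 per group.

#' Simulation configuration
#'
#' Collects all parameters of the synthetic study. Defaults reproduce the
#' emulated design: 562 strains, 13 flies per strain per temperature, 25
#' strains per extreme group sequenced as 4 replicate pools, mean merged
#' coverage 93 per group. The liability intercepts (`mu10`, `mu12`) and the
#' between-strain liability standard deviation (`strain_sd`) default to values
#' for which dormancy incidence is higher at 10 than at 12 degrees C and the
#' between-strain fraction of binary phenotype variance is ~0.24 at both
#' temperatures.
#'
#' @param n_strains number of isofemale strains (default 562).
#' @param n_sites number of polymorphic sites to simulate.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param maf_alpha,maf_beta shape parameters of the Beta founder
#'   allele-frequency distribution.
#' @param n_causal number of causal SNPs planted on the liability scale.
#' @param effect_sizes numeric vector (length `n_causal`) of liability-scale
#'   effects per copy of the alternate allele dosage (dosage scaled to 0..1).
#' @param causal_freq optional numeric vector overriding the founder frequency
#'   at the causal sites.
#' @param mu10,mu12 liability intercepts at 10 and 12 degrees C (logit scale).
#' @param strain_sd between-strain random-effect standard deviation.
#' @param flies_per_strain flies assayed per strain per temperature.
#' @param pool_strains strains per extreme group (default 25).
#' @param pool_replicates replicate pools per group (default 4).
#' @param mean_coverage mean read depth per site for each merged group.
#' @param error_rate per-read probability of a uniform miscall to another base.
#' @param egg_mu10,egg_mu12 Poisson means of egg counts of non-dormant flies.
#' @param cnv_regions optional list of copy-number regions, each a list with
#'   elements chrom, start, end (1-based, inclusive), carriers (strain ids)
#'   and copy_ratio.
#' @param seed master random seed; each simulation stage derives its own
#'   stream from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 562L, n_sites = 10000L,
                       chrom_lengths = c(`2L` = 6e5, `2R` = 6e5, `3L` = 6e5,
                                         `3R` = 6e5, X = 5e5),
                       maf_alpha = 0.5, maf_beta = 0.5,
                       n_causal = 0L, effect_sizes = numeric(0),
                       causal_freq = NULL,
                       mu10 = 1.1, mu12 = -0.9, strain_sd = 1.35,
                       flies_per_strain = 13L,
                       pool_strains = 25L, pool_replicates = 4L,
                       mean_coverage = 93, error_rate = 0.001,
                       egg_mu10 = 4, egg_mu12 = 9,
                       cnv_regions = NULL, seed = 1L) {
  assert_count(n_strains, "n_strains")
  assert_count(n_sites, "n_sites")
  assert_count(flies_per_strain, "flies_per_strain")
  assert_count(pool_strains, "pool_strains")
  assert_count(pool_replicates, "pool_replicates")
  assert_count(n_causal, "n_causal", positive = FALSE)
  if (!is.numeric(mean_coverage) || mean_coverage <= 0)
    stop("'mean_coverage' must be positive", call. = FALSE)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.25)
    stop("'error_rate' must lie in [0, 0.25)", call. = FALSE)
  if (!is.numeric(maf_alpha) || !is.numeric(maf_beta) || maf_alpha <= 0 || maf_beta <= 0)
    stop("configuration error: Beta shape parameters must be positive", call. = FALSE)
  if (length(effect_sizes) != n_causal)
    stop("'effect_sizes' must have length n_causal", call. = FALSE)
  if (!is.null(causal_freq) && length(causal_freq) != n_causal)
    stop("'causal_freq' must have length n_causal", call. = FALSE)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths < 1))
    stop("'chrom_lengths' must be a named vector of positive lengths", call. = FALSE)
  if (n_sites > sum(chrom_lengths))
    stop("n_sites exceeds total genome length", call. = FALSE)
  if (strain_sd < 0) stop("'strain_sd' must be nonnegative", call. = FALSE)
  structure(list(
    n_strains = as.integer(n_strains), n_sites = as.integer(n_sites),
    chrom_lengths = chrom_lengths, maf_alpha = maf_alpha, maf_beta = maf_beta,
    n_causal = as.integer(n_causal), effect_sizes = effect_sizes,
    causal_freq = causal_freq, mu10 = mu10, mu12 = mu12, strain_sd = strain_sd,
    flies_per_strain = as.integer(flies_per_strain),
    pool_strains = as.integer(pool_strains),
    pool_replicates = as.integer(pool_replicates),
    mean_coverage = mean_coverage, error_rate = error_rate,
    egg_mu10 = egg_mu10, egg_mu12 = egg_mu12,
    cnv_regions = cnv_regions, seed = as.integer(seed)), class = "sim_config")
}

#' Simulate isofemale strain genotypes
#'
#' Draws a population allele frequency per site from
#' Beta(`maf_alpha`, `maf_beta`) and gives each strain a founder-allele dosage
#' in 0..4 as the sum of four Bernoulli(freq) founder haplotypes (a strain
#' descends from one mated female, so it segregates at most four haplotypes
#' per locus; laboratory maintenance is modeled as leaving dosages unchanged).
#' Sites are placed uniformly without replacement along the chromosomes and
#' sorted by (chromosome, position). Deterministic given the config seed.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `strain_genotypes` with elements `dosages`
#'   (n_strains x n_sites integer matrix), `sites` (catalog data.frame with
#'   chrom, pos, ref, alt, freq, causal, effect) and `strains` (ids).
#' @export
simulate_strains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    lens <- config$chrom_lengths
    n_per <- stats::setNames(as.vector(
      table(factor(sample(names(lens), config$n_sites, replace = TRUE,
                          prob = lens / sum(lens)), levels = names(lens)))),
      names(lens))
    over <- n_per > lens
    while (any(over)) {  # cannot place more sites than positions on a chromosome
      excess <- sum(n_per[over] - lens[over])
      n_per[over] <- lens[over]
      room <- which(!over)
      n_per[room[1]] <- n_per[room[1]] + excess
      over <- n_per > lens
    }
    chrom <- rep(names(lens), n_per)
    pos <- unlist(lapply(names(lens), function(cn)
      sort(sample.int(lens[[cn]], n_per[[cn]]))), use.names = FALSE)
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]
    freq <- stats::rbeta(config$n_sites, config$maf_alpha, config$maf_beta)
    causal_idx <- if (config$n_causal > 0)
      sort(sample.int(config$n_sites, config$n_causal)) else integer(0)
    if (!is.null(config$causal_freq)) freq[causal_idx] <- config$causal_freq
    ref <- sample(NUCS, config$n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(NUCS, b), 1L), "")
    dosages <- matrix(
      stats::rbinom(config$n_strains * config$n_sites, 4L,
                    rep(freq, each = config$n_strains)),
      nrow = config$n_strains, ncol = config$n_sites)
    effect <- numeric(config$n_sites)
    effect[causal_idx] <- config$effect_sizes
    strains <- sprintf("S%04d", seq_len(config$n_strains))
    rownames(dosages) <- strains
    structure(list(
      dosages = dosages,
      sites = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                         alt = unname(alt), freq = freq,
                         causal = seq_len(config$n_sites) %in% causal_idx,
                         effect = effect),
      strains = strains), class = "strain_genotypes")
  })
}

#' Simulate per-fly dormancy phenotypes
#'
#' Liability-threshold model: fly dormancy is Bernoulli with probability
#' `plogis(mu_T + sum(effect_i * (dosage_i / 4 - freq_i)) + strain_effect)`,
#' where the strain effect is Normal(0, `strain_sd`) and shared by all flies
#' of a strain. Causal contributions are centered at the founder allele
#' frequency so the intercepts `mu10`/`mu12` stay the population-mean
#' liabilities whatever effects are planted. Non-dormant flies lay a Poisson
#' number of eggs with a temperature-dependent mean (fewer at 10 than at 12
#' degrees C); dormant flies lay none.
#'
#' @param genotypes a `strain_genotypes` object.
#' @param config the [sim_config()] used to generate them.
#' @return a data.frame with columns strain, temperature ("10C"/"12C"),
#'   fly_id, dormant (logical), eggs.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "strain_genotypes"), inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 2L), {
    ns <- config$n_strains
    f <- config$flies_per_strain
    b <- stats::rnorm(ns, 0, config$strain_sd)
    g <- if (config$n_causal > 0) {
      ci <- which(genotypes$sites$causal)
      dose_centered <- sweep(genotypes$dosages[, ci, drop = FALSE] / 4, 2,
                             genotypes$sites$freq[ci])
      as.vector(dose_centered %*% genotypes$sites$effect[ci])
    } else numeric(ns)
    out <- vector("list", 2L)
    temps <- c("10C", "12C")
    mus <- c(config$mu10, config$mu12)
    egg_mus <- c(config$egg_mu10, config$egg_mu12)
    for (t in 1:2) {
      p <- stats::plogis(mus[t] + g + b)
      dormant <- stats::rbinom(ns * f, 1L, rep(p, each = f)) == 1L
      eggs <- integer(ns * f)
      eggs[!dormant] <- stats::rpois(sum(!dormant), egg_mus[t])
      out[[t]] <- data.frame(
        strain = rep(genotypes$strains, each = f),
        temperature = temps[t],
        fly_id = rep(seq_len(f), times = ns),
        dormant = dormant, eggs = eggs)
    }
    rbind(out[[1]], out[[2]])
  })
}

#' Generate pooled sequencing counts for the extreme groups
#'
#' Each of the `pool_replicates` replicate pools per group draws one fly per
#' selected strain (fly dosage ~ Binomial(2, strain dosage / 4)). Per library
#' and site, read depth is Poisson(`mean_coverage` / `pool_replicates`), reads
#' are drawn from the pool allele frequency, and each read miscalls to a
#' uniformly chosen other nucleotide with probability `error_rate`. Copy-number
#' regions multiply the depth contribution (and allele-frequency weight) of
#' carrier strains by their copy ratio.
#'
#' @param genotypes a `strain_genotypes` object.
#' @param selected_D,selected_ND disjoint character vectors of strain ids for
#'   the Dormant and Non-Dormant pools.
#' @param config the [sim_config()] object.
#' @return a list with elements `sync` (8-library `sync` object D1..D4,
#'   ND1..ND4), `groups` (named vector library -> "D"/"ND") and `truth`
#'   (list with causal-site and CNV data.frames).
#' @export
generate_pool_counts <- function(genotypes, selected_D, selected_ND, config) {
  stopifnot(inherits(genotypes, "strain_genotypes"), inherits(config, "sim_config"))
  if (length(intersect(selected_D, selected_ND)))
    stop("design error: selected strain lists overlap between D and ND", call. = FALSE)
  if (!all(c(selected_D, selected_ND) %in% genotypes$strains))
    stop("design error: unknown strain id in selection", call. = FALSE)
  n <- config$n_sites
  r <- config$pool_replicates
  sites <- genotypes$sites
  # per-strain, per-site copy weight from planted CNV regions
  cnv_weight <- function(sel) {
    W <- matrix(1, nrow = length(sel), ncol = n)
    for (cnv in config$cnv_regions %||% list()) {
      rows <- which(sel %in% cnv$carriers)
      cols <- which(sites$chrom == cnv$chrom & sites$pos >= cnv$start &
                      sites$pos <= cnv$end)
      if (length(rows) && length(cols)) W[rows, cols] <- cnv$copy_ratio
    }
    W
  }
  others <- t(vapply(NUCS, function(b) match(setdiff(NUCS, b), NUCS), integer(3)))
  ref_idx <- match(sites$ref, NUCS)
  alt_idx <- match(sites$alt, NUCS)
  libs <- c(paste0("D", seq_len(r)), paste0("ND", seq_len(r)))
  counts <- array(0L, dim = c(n, 6L, 2L * r), dimnames = list(NULL, BASES6, libs))
  withr::with_seed(derive_seed(config$seed, 3L), {
    lib <- 0L
    for (grp in list(D = selected_D, ND = selected_ND)) {
      k <- length(grp)
      dos <- genotypes$dosages[grp, , drop = FALSE]
      W <- cnv_weight(grp)
      for (rep_i in seq_len(r)) {
        lib <- lib + 1L
        G <- matrix(stats::rbinom(k * n, 2L, as.vector(dos) / 4), nrow = k)
        wsum <- colSums(W)
        freq <- colSums(W * G) / (2 * wsum)
        lambda <- (config$mean_coverage / r) * wsum / k
        depth <- stats::rpois(n, lambda)
        alt_reads <- stats::rbinom(n, depth, freq)
        ref_reads <- depth - alt_reads
        e_ref <- stats::rbinom(n, ref_reads, config$error_rate)
        e_alt <- stats::rbinom(n, alt_reads, config$error_rate)
        m <- matrix(0L, nrow = n, ncol = 6L)
        m[cbind(seq_len(n), ref_idx)] <- ref_reads - e_ref
        m[cbind(seq_len(n), alt_idx)] <- m[cbind(seq_len(n), alt_idx)] + (alt_reads - e_alt)
        for (src in list(list(e = e_ref, from = ref_idx), list(e = e_alt, from = alt_idx))) {
          x1 <- stats::rbinom(n, src$e, 1 / 3)
          x2 <- stats::rbinom(n, src$e - x1, 1 / 2)
          x3 <- src$e - x1 - x2
          oth <- others[src$from, , drop = FALSE]
          for (j in 1:3) {
            idx <- cbind(seq_len(n), oth[, j])
            m[idx] <- m[idx] + list(x1, x2, x3)[[j]]
          }
        }
        counts[, , lib] <- m
      }
    }
  })
  truth_causal <- sites[sites$causal, c("chrom", "pos", "freq", "effect")]
  if (nrow(truth_causal)) {
    ci <- which(sites$causal)
    truth_causal$freq_D <- colMeans(genotypes$dosages[selected_D, ci, drop = FALSE]) / 4
    truth_causal$freq_ND <- colMeans(genotypes$dosages[selected_ND, ci, drop = FALSE]) / 4
  }
  truth_cnv <- if (length(config$cnv_regions %||% list())) {
    do.call(rbind, lapply(config$cnv_regions, function(cnv)
      data.frame(chrom = cnv$chrom, start = cnv$start, end = cnv$end,
                 copy_ratio = cnv$copy_ratio,
                 n_carriers_D = length(intersect(cnv$carriers, selected_D)),
                 n_carriers_ND = length(intersect(cnv$carriers, selected_ND)))))
  } else data.frame()
  list(sync = sync_data(sites$chrom, sites$pos, sites$ref, counts, libs),
       groups = stats::setNames(rep(c("D", "ND"), each = r), libs),
       truth = list(causal = truth_causal, cnv = truth_cnv))
}

#' Run the full synthetic study
#'
#' Convenience wrapper: simulates strains and phenotypes, computes strain
#' dormancy profiles, selects the extreme groups, and generates the pooled
#' sequencing counts.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements genotypes, phenotypes, profiles, groups
#'   (an `extreme_groups` object), sync, lib_groups (library -> group) and
#'   truth.
#' @export
simulate_study <- function(config) {
  genotypes <- simulate_strains(config)
  phenotypes <- simulate_phenotypes(genotypes, config)
  profiles <- compute_dormancy_levels(phenotypes)
  groups <- select_extreme_groups(profiles, k = config$pool_strains)
  pools <- generate_pool_counts(genotypes, groups$dormant_strains,
                                groups$nondormant_strains, config)
  list(genotypes = genotypes, phenotypes = phenotypes, profiles = profiles,
       groups = groups, sync = pools$sync, lib_groups = pools$groups,
       truth = pools$truth)
}

#' Simulate per-individual window depths for CNV verification
#'
#' Emulates sequencing single phenotyped flies: each individual's mean depth
#' over a window is Poisson(window * depth * copy factor) / window, where the
#' copy factor is `copy_ratio` for carrier individuals and 1 otherwise.
#'
#' @param n number of individuals (the emulated follow-up used 12).
#' @param mean_depth per-site expected depth of a non-carrier individual.
#' @param carriers integer indices of carrier individuals.
#' @param copy_ratio depth multiplier for carriers.
#' @param window window size in bp.
#' @param seed integer seed.
#' @return named numeric vector of per-individual mean depths.
#' @export
simulate_individual_depths <- function(n = 12L, mean_depth = 10,
                                       carriers = integer(0), copy_ratio = 1,
                                       window = 200L, seed = 1L) {
  assert_count(n, "n")
  lam <- rep(mean_depth, n)
  lam[carriers] <- mean_depth * copy_ratio
  withr::with_seed(seed,
    stats::setNames(stats::rpois(n, window * lam) / window,
                    sprintf("ind_%02d", seq_len(n))))
}

#' Theoretical between-strain variance fraction of the binary phenotype
#'
#' For the logistic liability model with strain effects Normal(0, sd), the
#' intraclass correlation of the per-fly binary outcome is
#' Var(p) / (Var(p) + E(p(1 - p))) with p = plogis(mu + b), computed by
#' numeric integration over the strain-effect distribution.
#'
#' @param mu liability intercept (logit scale).
#' @param strain_sd strain random-effect standard deviation.
#' @return the ICC in [0, 1).
#' @export
icc_binary_theory <- function(mu, strain_sd) {
  if (strain_sd == 0) return(0)
  m1 <- stats::integrate(function(b) stats::plogis(mu + b) * stats::dnorm(b, 0, strain_sd),
                         -Inf, Inf)$value
  m2 <- stats::integrate(function(b) stats::plogis(mu + b)^2 * stats::dnorm(b, 0, strain_sd),
                         -Inf, Inf)$value
  var_b <- m2 - m1^2
  var_w <- m1 - m2
  var_b / (var_b + var_w)
}

#' Strain standard deviation achieving a target ICC
#'
#' Inverts [icc_binary_theory()] in `strain_sd` by root finding.
#'
#' @param icc target between-strain variance fraction in (0, 1).
#' @param mu liability intercept (logit scale).
#' @return the strain standard deviation.
#' @export
strain_sd_for_icc <- function(icc, mu = 0) {
  assert_prob(icc, "icc")
  stats::uniroot(function(s) icc_binary_theory(mu, s) - icc,
                 lower = 1e-3, upper = 25, tol = 1e-7)$root
}

#' Generate a synthetic repeat/TE mask
#'
#' Random non-overlapping intervals (0-based, half-open) covering roughly
#' `fraction` of each chromosome, as a stand-in for a RepeatMasker-derived
#' mask BED.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param fraction approximate masked fraction of the genome.
#' @param mean_len mean interval length (bp).
#' @param seed integer seed.
#' @return a BED data.frame (chrom, start, end).
#' @export
synth_mask_bed <- function(chrom_lengths, fraction = 0.05, mean_len = 500, seed = 1L) {
  withr::with_seed(seed, {
    out <- lapply(names(chrom_lengths), function(cn) {
      len <- chrom_lengths[[cn]]
      n_iv <- max(0L, round(fraction * len / mean_len))
      if (n_iv == 0L) return(NULL)
      start <- sort(sample.int(len - 1L, n_iv))
      end <- pmin(start + pmax(1L, stats::rpois(n_iv, mean_len)), len)
      keep <- c(TRUE, start[-1] >= end[-n_iv])  # drop overlaps
      data.frame(chrom = cn, start = start[keep], end = end[keep])
    })
    do.call(rbind, out[!vapply(out, is.null, TRUE)])
  })
}

#' Generate a toy gene annotation
#'
#' Non-overlapping gene intervals per chromosome, written as GFF3 gene
#' features, for exercising gene-level candidate aggregation.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_genes total number of genes.
#' @param mean_len mean gene length (bp).
#' @param seed integer seed.
#' @param path optional output path; when given, a GFF3 file is written.
#' @return a data.frame (gene_id, chrom, start, end), invisibly if written.
#' @export
synth_genes_gff <- function(chrom_lengths, n_genes = 100L, mean_len = 2000,
                            seed = 1L, path = NULL) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    genes <- do.call(rbind, lapply(names(chrom_lengths), function(cn) {
      m <- sum(chrom == cn)
      if (!m) return(NULL)
      start <- sort(sample.int(max(1, chrom_lengths[[cn]] - mean_len), m))
      end <- pmin(start + pmax(50L, stats::rpois(m, mean_len)), chrom_lengths[[cn]])
      keep <- c(TRUE, start[-1] > end[-m])
      data.frame(chrom = cn, start = start[keep], end = end[keep])
    }))
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end")]
  })
  if (!is.null(path)) {
    lines <- c("##gff-version 3",
               sprintf("%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$gene_id))
    writeLines(lines, path)
    return(invisible(genes))
  }
  genes
}
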