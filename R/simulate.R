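#' Simulation configuration for the synthetic cohort
#'
#' Describes a block-LD genotype simulation with planted causal loci and a
#' bimodal, case-oversampled gestational-age phenotype. Genotypes are built
#' from per-block founder haplotype pools: each individual haplotype picks a
#' pool member per block and keeps it across block boundaries with
#' probability `1 - recomb_prob`, which creates strong within-block linkage
#' disequilibrium and tunable between-block decay.
#'
#' @param n_samples Number of individuals.
#' @param n_chromosomes,blocks_per_chr,snps_per_block Genome layout.
#' @param founder_haplotypes_per_block Size of each block's haplotype pool;
#'   small pools give strong LD.
#' @param maf_range Pair in (0, 0.5]; per-SNP pool allele frequencies are
#'   drawn uniformly from this range.
#' @param recomb_prob Probability of re-drawing the pool member at each block
#'   boundary (0 = no recombination, 1 = independent blocks).
#' @param causal_spec List of `list(snp = <global SNP index>, model =
#'   "additive"|"recessive"|"dominant", effect = <days>)`. Effects act on the
#'   A2-allele count coding of the named SNP.
#' @param noise_sd Residual SD of gestational age in days.
#' @param baseline_ga Baseline gestational age in days.
#' @param sampling_ranges Data frame with columns `lo`, `hi`, `n`: closed
#'   day-ranges with target sample counts; defaults to the two-range
#'   case-oversampled design (154-258 preterm, 273-286 term) with an even
#'   split. Counts must sum to `n_samples`.
#' @param onset_props Named proportions for delivery-onset labels
#'   (`labor`, `PROM`); default 0.807/0.193.
#' @param genome_props Named proportions for genome-type labels
#'   (`mother`, `child`).
#' @param snp_spacing_bp,block_gap_bp Physical spacing of SNPs within a block
#'   and gap between adjacent blocks (defaults 10 kb and 500 kb, so blocks
#'   are farther apart than a 250 kb clumping window).
#' @param x_chromosome If `TRUE` the last chromosome is labelled `"X"`.
#' @param n_duplicate_pairs Opt-in relatedness injection: the last *k*
#'   samples are overwritten with copies of the first *k* (PI_HAT ~ 1 pairs).
#' @param mask_rate Opt-in uniform missing-call rate over the whole matrix.
#' @param mask_snp_idx,mask_snp_rate Opt-in extra masking of specific SNPs.
#' @param mask_sample_idx,mask_sample_rate Opt-in extra masking of specific
#'   samples.
#' @param seed Integer seed; every simulation draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 200L,
                       n_chromosomes = 2L,
                       blocks_per_chr = 5L,
                       snps_per_block = 10L,
                       founder_haplotypes_per_block = 8L,
                       maf_range = c(0.1, 0.5),
                       recomb_prob = 0.5,
                       causal_spec = list(),
                       noise_sd = 12,
                       baseline_ga = 274,
                       sampling_ranges = NULL,
                       onset_props = c(labor = 0.807, PROM = 0.193),
                       genome_props = c(mother = 0.5, child = 0.5),
                       snp_spacing_bp = 10000L,
                       block_gap_bp = 500000L,
                       x_chromosome = FALSE,
                       n_duplicate_pairs = 0L,
                       mask_rate = 0,
                       mask_snp_idx = integer(0), mask_snp_rate = 0.05,
                       mask_sample_idx = integer(0), mask_sample_rate = 0.05,
                       seed = 1L) {
  if (is.null(sampling_ranges)) {
    n1 <- floor(n_samples / 2)
    sampling_ranges <- data.frame(lo = c(154, 273), hi = c(258, 286),
                                  n = c(n1, n_samples - n1))
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              blocks_per_chr = as.integer(blocks_per_chr),
              snps_per_block = as.integer(snps_per_block),
              founder_haplotypes_per_block = as.integer(founder_haplotypes_per_block),
              maf_range = as.numeric(maf_range),
              recomb_prob = as.numeric(recomb_prob),
              causal_spec = causal_spec,
              noise_sd = as.numeric(noise_sd),
              baseline_ga = as.numeric(baseline_ga),
              sampling_ranges = sampling_ranges,
              onset_props = onset_props,
              genome_props = genome_props,
              snp_spacing_bp = as.integer(snp_spacing_bp),
              block_gap_bp = as.integer(block_gap_bp),
              x_chromosome = isTRUE(x_chromosome),
              n_duplicate_pairs = as.integer(n_duplicate_pairs),
              mask_rate = mask_rate,
              mask_snp_idx = as.integer(mask_snp_idx),
              mask_snp_rate = mask_snp_rate,
              mask_sample_idx = as.integer(mask_sample_idx),
              mask_sample_rate = mask_sample_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1 || n_chromosomes < 1 || blocks_per_chr < 1 ||
        snps_per_block < 1 || founder_haplotypes_per_block < 1)
      stop("sim_config: dimensions must be positive")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("sim_config: maf_range must lie within (0, 0.5]")
    if (recomb_prob < 0 || recomb_prob > 1)
      stop("sim_config: recomb_prob must be in [0, 1]")
    if (sum(sampling_ranges$n) != n_samples)
      stop("sim_config: sampling_ranges counts must sum to n_samples")
    if (any(sampling_ranges$lo > sampling_ranges$hi))
      stop("sim_config: sampling range lo > hi")
    n_snps <- n_chromosomes * blocks_per_chr * snps_per_block
    for (cs in causal_spec) {
      if (!all(c("snp", "model", "effect") %in% names(cs)))
        stop("sim_config: causal_spec entries need snp, model, effect")
      if (cs$snp < 1 || cs$snp > n_snps)
        stop("sim_config: causal SNP index out of range")
      if (!cs$model %in% c("additive", "recessive", "dominant"))
        stop("sim_config: unknown genetic model '", cs$model, "'")
      if (!is.finite(cs$effect)) stop("sim_config: effect sizes must be finite")
    }
    invisible(TRUE)
  })
}

# deterministic genome layout shared by the genotype and annotation
# generators: per-chromosome SNP positions and block index
genome_layout <- function(cfg) {
  nb <- cfg$blocks_per_chr; m_blk <- cfg$snps_per_block
  n_snps_chr <- nb * m_blk
  chrs <- as.character(seq_len(cfg$n_chromosomes))
  if (cfg$x_chromosome) chrs[length(chrs)] <- "X"
  bp <- integer(n_snps_chr)
  pos <- 0L
  for (b in seq_len(nb)) {
    start <- pos + cfg$block_gap_bp
    bp[(b - 1) * m_blk + seq_len(m_blk)] <-
      start + cfg$snp_spacing_bp * (seq_len(m_blk) - 1L)
    pos <- start + cfg$snp_spacing_bp * (m_blk - 1L)
  }
  list(chrs = chrs, bp = bp,
       block = rep(seq_len(nb), each = m_blk),
       n_snps_chr = n_snps_chr)
}

#' Simulate LD-blocked diploid genotypes
#'
#' Draws genotypes under the founder-haplotype-pool block model described in
#' [sim_config()]. Within a block, adjacent SNPs show elevated r-squared
#' because haplotypes are copies of a small founder pool; across block
#' boundaries the pool member is re-drawn with probability `recomb_prob`.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "genotypes"), {
    n <- cfg$n_samples
    nb <- cfg$blocks_per_chr
    m_blk <- cfg$snps_per_block
    K <- cfg$founder_haplotypes_per_block
    lay <- genome_layout(cfg)
    n_snps_chr <- lay$n_snps_chr
    chrs <- lay$chrs

    calls <- matrix(0L, n, 0)
    map <- list()
    acgt <- c("A", "C", "G", "T")
    # causal SNPs must segregate: their pool column carries an exact allele
    # count clamped to [1, K-1] instead of a Binomial draw
    causal_global <- vapply(cfg$causal_spec, `[[`, numeric(1), "snp")
    for (ci in seq_along(chrs)) {
      chr_off <- (ci - 1L) * n_snps_chr
      pools <- lapply(seq_len(nb), function(b) {
        f <- runif(m_blk, cfg$maf_range[1], cfg$maf_range[2])
        pool <- matrix(rbinom(K * m_blk, 1L, rep(f, each = K)), K, m_blk)
        blk_off <- chr_off + (b - 1L) * m_blk
        for (j in seq_len(m_blk)) {
          if ((blk_off + j) %in% causal_global && K >= 2L) {
            ones <- min(max(round(f[j] * K), 1L), K - 1L)
            pool[, j] <- sample(rep(c(1L, 0L), c(ones, K - ones)))
          }
        }
        pool
      })
      # per haplotype, chain of pool members along blocks
      hap_calls <- function() {
        h <- matrix(0L, n, n_snps_chr)
        k <- sample.int(K, n, replace = TRUE)
        for (b in seq_len(nb)) {
          if (b > 1) {
            sw <- runif(n) < cfg$recomb_prob
            k[sw] <- sample.int(K, sum(sw), replace = TRUE)
          }
          h[, (b - 1) * m_blk + seq_len(m_blk)] <- pools[[b]][k, , drop = FALSE]
        }
        h
      }
      g <- hap_calls() + hap_calls()
      calls <- cbind(calls, g)
      bp <- lay$bp
      al <- t(vapply(seq_len(n_snps_chr),
                     function(i) sample(acgt, 2), character(2)))
      map[[ci]] <- data.frame(
        id = sprintf("rs%s_%04d", chrs[ci], seq_len(n_snps_chr)),
        chr = chrs[ci], bp = bp, a1 = al[, 1], a2 = al[, 2],
        stringsAsFactors = FALSE)
    }
    snp_map <- do.call(rbind, map)
    samples <- data.frame(id = sprintf("ind%05d", seq_len(n)),
                          founder = TRUE,
                          sex = sample(1:2, n, replace = TRUE),
                          stringsAsFactors = FALSE)

    if (cfg$n_duplicate_pairs > 0) {
      k <- cfg$n_duplicate_pairs
      if (2 * k > n) stop("sim_config: too many duplicate pairs")
      calls[n - k + seq_len(k), ] <- calls[seq_len(k), , drop = FALSE]
    }
    if (cfg$mask_rate > 0)
      calls[runif(length(calls)) < cfg$mask_rate] <- NA_integer_
    for (j in cfg$mask_snp_idx)
      calls[runif(n) < cfg$mask_snp_rate, j] <- NA_integer_
    for (i in cfg$mask_sample_idx)
      calls[i, runif(ncol(calls)) < cfg$mask_sample_rate] <- NA_integer_

    genotype_matrix(calls, snp_map, samples)
  })
}

#' Simulate the case-oversampled gestational-age phenotype
#'
#' Latent gestational age is `baseline_ga` plus the model-coded causal
#' effects plus Gaussian noise, rounded to integer days. Samples are then
#' rejection-sampled (noise re-drawn) until every configured day-range holds
#' exactly its target count, reproducing the cohort's bimodal
#' case-oversampled design. Delivery-onset and genome-type labels are drawn
#' from the configured proportions.
#'
#' @param G A [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A data frame with columns `sample_id`, `ga_days` (integer days),
#'   `onset` (`labor`/`PROM`), `genome` (`mother`/`child`).
#' @export
simulate_phenotype <- function(G, cfg) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "phenotype"), {
    n <- nrow(G$calls)
    genetic <- rep(0, n)
    for (cs in cfg$causal_spec) {
      g <- G$calls[, cs$snp]
      g[is.na(g)] <- 0L
      d <- switch(cs$model,
                  additive  = g,
                  recessive = as.integer(g == 2L),
                  dominant  = as.integer(g >= 1L))
      genetic <- genetic + cs$effect * d
    }
    rng <- cfg$sampling_ranges
    quota <- rng$n
    ga <- integer(n)
    budget <- 100 * n  # total rejection budget
    used <- 0L
    for (i in seq_len(n)) {
      repeat {
        used <- used + 1L
        if (used > budget)
          stop("simulate_phenotype: sampling-range targets unattainable ",
               "within the rejection budget")
        x <- round(cfg$baseline_ga + genetic[i] + rnorm(1, 0, cfg$noise_sd))
        r <- which(x >= rng$lo & x <= rng$hi & quota > 0L)
        if (length(r)) { quota[r[1]] <- quota[r[1]] - 1L; ga[i] <- x; break }
      }
    }
    onset <- sample(names(cfg$onset_props), n, replace = TRUE,
                    prob = cfg$onset_props)
    genome <- sample(names(cfg$genome_props), n, replace = TRUE,
                     prob = cfg$genome_props)
    data.frame(sample_id = G$samples$id, ga_days = as.integer(ga),
               onset = onset, genome = genome, stringsAsFactors = FALSE)
  })
}
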