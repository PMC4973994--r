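# Genotype / sample quality control: missingness, heterozygosity,
# relatedness, Hardy-Weinberg exact test, PCA ancestry outliers, and the
# genomic inflation factor.

#' Quality-control parameters
#'
#' Defaults follow the study design this package reproduces: 3% missingness
#' for SNPs and samples, +/-3 SD heterozygosity, PI_HAT 0.05 ("closer than
#' second cousins"; second cousins expect ~0.031), HWE p < 1e-6, first three
#' principal components with a 10 SD distance cut from the reference
#' centroid, and a MAF > 0.06 restriction for the inflation factor.
#'
#' @param missingness_threshold Maximum missing-call proportion.
#' @param het_sd_threshold Heterozygosity outlier cut in SD multiples.
#' @param relatedness_pihat_threshold PI_HAT above which one random member
#'   of a pair is removed.
#' @param hwe_p_threshold Hardy-Weinberg exact-test removal threshold.
#' @param pca_n_components Number of leading principal components.
#' @param pca_sd_threshold Distance cut in SD multiples of the reference
#'   distance distribution.
#' @param lambda_maf_min MAF restriction for the genomic inflation factor.
#' @param ld_thin_r2,ld_thin_window Greedy LD thinning used before
#'   relatedness and PCA: within a sliding window of `ld_thin_window` SNPs,
#'   keep one SNP of every pair with genotype r-squared above `ld_thin_r2`.
#' @param hwe_founders_only Test HWE on founders only.
#' @param seed Seed for the random member choice in relatedness removal.
#' @return A `qc_params` list.
#' @export
qc_params <- function(missingness_threshold = 0.03,
                      het_sd_threshold = 3,
                      relatedness_pihat_threshold = 0.05,
                      hwe_p_threshold = 1e-6,
                      pca_n_components = 3L,
                      pca_sd_threshold = 10,
                      lambda_maf_min = 0.06,
                      ld_thin_r2 = 0.2,
                      ld_thin_window = 50L,
                      hwe_founders_only = FALSE,
                      seed = 1L) {
  stopifnot(missingness_threshold >= 0, missingness_threshold <= 1,
            het_sd_threshold > 0, relatedness_pihat_threshold > 0,
            hwe_p_threshold > 0, hwe_p_threshold < 1,
            pca_n_components >= 1, pca_sd_threshold > 0,
            lambda_maf_min >= 0, lambda_maf_min < 0.5)
  structure(list(missingness_threshold = missingness_threshold,
                 het_sd_threshold = het_sd_threshold,
                 relatedness_pihat_threshold = relatedness_pihat_threshold,
                 hwe_p_threshold = hwe_p_threshold,
                 pca_n_components = as.integer(pca_n_components),
                 pca_sd_threshold = pca_sd_threshold,
                 lambda_maf_min = lambda_maf_min,
                 ld_thin_r2 = ld_thin_r2,
                 ld_thin_window = as.integer(ld_thin_window),
                 hwe_founders_only = isTRUE(hwe_founders_only),
                 seed = as.integer(seed)),
            class = "qc_params")
}

qc_stage_report <- function(stage, n_samples_in, n_snps_in, G_out,
                            removed_samples = character(0),
                            removed_snps = character(0),
                            extra = list()) {
  rep <- c(list(stage = stage,
                n_samples_in = n_samples_in, n_snps_in = n_snps_in,
                n_samples_out = nrow(G_out$calls),
                n_snps_out = ncol(G_out$calls),
                removed_samples = removed_samples,
                removed_snps = removed_snps), extra)
  stopifnot(rep$n_samples_in - length(removed_samples) == rep$n_samples_out,
            rep$n_snps_in - length(removed_snps) == rep$n_snps_out)
  log_note("qc", stage, ": removed ", length(removed_samples), " sample(s), ",
           length(removed_snps), " SNP(s); ", rep$n_samples_out, " x ",
           rep$n_snps_out, " remain")
  rep
}

#' Missingness filter (samples first, then SNPs)
#'
#' Samples whose call rate falls below `1 - missingness_threshold` are
#' removed first; SNP missingness is then recomputed on the remaining
#' samples and SNPs removed by the same rule.
#'
#' @param G A [genotype_matrix()].
#' @param params [qc_params()].
#' @return List with the filtered `G` and a stage `report`.
#' @export
filter_missingness <- function(G, params = qc_params()) {
  thr <- params$missingness_threshold
  miss_sample <- rowMeans(is.na(G$calls))
  drop_s <- G$samples$id[miss_sample > thr]
  G1 <- if (length(drop_s)) subset_genotypes(G, samples = !(G$samples$id %in% drop_s)) else G
  if (nrow(G1$calls) == 0L) stop("filter_missingness: all samples removed")
  miss_snp <- colMeans(is.na(G1$calls))
  drop_v <- G1$snp_map$id[miss_snp > thr]
  G2 <- if (length(drop_v)) subset_genotypes(G1, snps = !(G1$snp_map$id %in% drop_v)) else G1
  list(G = G2,
       report = qc_stage_report("missingness", nrow(G$calls), ncol(G$calls),
                                G2, drop_s, drop_v))
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditional on allele counts: the p-value is the sum
#' of probabilities of all heterozygote configurations no more probable than
#' the observed one. Computed with the standard recurrence over heterozygote
#' counts; a monomorphic SNP returns p = 1.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (A1 homozygote, heterozygote,
#'   A2 homozygote).
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("hwe_exact_test: total count must be >= 1")
  n1 <- 2L * n_hom1 + n_het          # A1 allele count
  n2 <- 2L * n_hom2 + n_het
  nr <- min(n1, n2)                  # rare allele count
  if (nr == 0L) return(1)
  # heterozygote counts share the parity of nr
  hets <- seq.int(nr %% 2L, nr, by = 2L)
  probs <- numeric(length(hets))
  # start at the modal region: expected het count under HWE
  h0 <- round(n1 * n2 / (2 * n) / 1) # expectation ~ n1*n2/(2n)
  h0 <- hets[which.min(abs(hets - h0))]
  i0 <- match(h0, hets)
  probs[i0] <- 1
  # P(h-2)/P(h) = h(h-1) / (4 (hom_r + 1)(hom_c + 1)) with hom counts at h-2
  if (i0 >= 2L) for (i in i0:2L) {
    h <- hets[i]
    homr <- (nr - h) / 2            # rare homozygotes at h
    homc <- n - h - homr            # common homozygotes at h
    probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (homr + 1) * (homc + 1))
  }
  if (i0 < length(hets)) for (i in i0:(length(hets) - 1L)) {
    h <- hets[i]
    homr <- (nr - h) / 2
    homc <- n - h - homr
    probs[i + 1L] <- probs[i] * 4 * homr * homc / ((h + 1) * (h + 2))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) stop("hwe_exact_test: inconsistent genotype counts")
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Hardy-Weinberg filter
#'
#' @param G A [genotype_matrix()].
#' @param params [qc_params()]; `hwe_founders_only` restricts the test to
#'   founder samples.
#' @return List with filtered `G`, stage `report` and the per-SNP p-values.
#' @export
filter_hwe <- function(G, params = qc_params()) {
  calls <- if (params$hwe_founders_only)
    G$calls[G$samples$founder, , drop = FALSE] else G$calls
  p <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    hwe_exact_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  drop <- G$snp_map$id[p < params$hwe_p_threshold]
  G2 <- if (length(drop)) subset_genotypes(G, snps = !(G$snp_map$id %in% drop)) else G
  list(G = G2, p = stats::setNames(p, G$snp_map$id),
       report = qc_stage_report("hwe", nrow(G$calls), ncol(G$calls), G2,
                                character(0), drop))
}

#' Heterozygosity outlier filter
#'
#' Per-sample observed heterozygosity rate over autosomal SNPs; samples
#' deviating more than `het_sd_threshold` SD from the mean are removed.
#' When the SD is zero, nothing is removed.
#'
#' @param G A [genotype_matrix()].
#' @param params [qc_params()].
#' @return List with filtered `G` and a stage `report`.
#' @export
filter_heterozygosity <- function(G, params = qc_params()) {
  auto <- G$snp_map$chr != "X"
  calls <- G$calls[, auto, drop = FALSE]
  het <- rowSums(calls == 1L, na.rm = TRUE) / rowSums(!is.na(calls))
  mu <- mean(het, na.rm = TRUE); s <- stats::sd(het, na.rm = TRUE)
  drop <- if (is.na(s) || s == 0) character(0)
          else G$samples$id[!is.na(het) & abs(het - mu) > params$het_sd_threshold * s]
  G2 <- if (length(drop)) subset_genotypes(G, samples = !(G$samples$id %in% drop)) else G
  list(G = G2, het = stats::setNames(het, G$samples$id),
       report = qc_stage_report("heterozygosity", nrow(G$calls),
                                ncol(G$calls), G2, drop, character(0)))
}

# Greedy LD thinning: scan SNPs in map order per chromosome; drop a SNP if
# its genotype r^2 with any kept SNP among the previous `window` kept SNPs
# exceeds r2. Returns kept SNP indices.
thin_snps <- function(G, r2 = 0.2, window = 50L) {
  keep <- integer(0)
  for (ch in unique(G$snp_map$chr)) {
    idx <- which(G$snp_map$chr == ch)
    kept_ch <- integer(0)
    for (j in idx) {
      recent <- utils::tail(kept_ch, window)
      ok <- TRUE
      x <- G$calls[, j]
      if (stats::var(x, na.rm = TRUE) %in% c(0, NA)) next
      for (k in recent) {
        r <- suppressWarnings(stats::cor(x, G$calls[, k],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r * r > r2) { ok <- FALSE; break }
      }
      if (ok) kept_ch <- c(kept_ch, j)
    }
    keep <- c(keep, kept_ch)
  }
  sort(keep)
}

# Method-of-moments PI_HAT for all pairs within a sample subset.
# IBS counts via indicator cross-products; IBS|IBD expectations from
# population allele frequencies (no small-sample correction).
pihat_matrix <- function(calls, freqs) {
  M0 <- (!is.na(calls)) & calls == 0L; M0[is.na(calls)] <- FALSE
  M1 <- (!is.na(calls)) & calls == 1L; M1[is.na(calls)] <- FALSE
  M2 <- (!is.na(calls)) & calls == 2L; M2[is.na(calls)] <- FALSE
  storage.mode(M0) <- storage.mode(M1) <- storage.mode(M2) <- "double"
  V <- M0 + M1 + M2
  ibs2 <- tcrossprod(M0) + tcrossprod(M1) + tcrossprod(M2)
  ibs0 <- tcrossprod(M0, M2) + tcrossprod(M2, M0)
  valid <- tcrossprod(V)
  ibs1 <- valid - ibs2 - ibs0
  p <- freqs; q <- 1 - p
  e0_0 <- sum(2 * p^2 * q^2)
  e1_0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- length(p)
  frac <- valid / m                       # scale expectations to valid pairs
  P0 <- ibs0 / (frac * e0_0)
  P1 <- (ibs1 - P0 * frac * e1_0) / (frac * e1_1)
  P2 <- (ibs2 - P0 * frac * e2_0 - P1 * frac * e2_1) / valid
  P0 <- pmin(pmax(P0, 0), 1); P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  P1 <- P1 / tot; P2 <- P2 / tot
  P2 + 0.5 * P1
}

#' Relatedness filter
#'
#' Method-of-moments genome-wide IBD proportion (PI_HAT) on an LD-thinned
#' SNP subset, computed within each group (e.g. mothers with mothers,
#' children with children). For every pair above the threshold, one random
#' member is removed (choice fixed by `params$seed`).
#'
#' @param G A [genotype_matrix()].
#' @param params [qc_params()].
#' @param groups Optional character vector (one per sample) restricting
#'   comparisons to within-group pairs; `NULL` means one group.
#' @return List with filtered `G`, stage `report` and the flagged pair table.
#' @export
filter_relatedness <- function(G, params = qc_params(), groups = NULL) {
  keep_idx <- thin_snps(G, params$ld_thin_r2, params$ld_thin_window)
  calls <- G$calls[, keep_idx, drop = FALSE]
  freqs <- colMeans(calls, na.rm = TRUE) / 2
  poly <- freqs > 0 & freqs < 1 & !is.na(freqs)
  calls <- calls[, poly, drop = FALSE]; freqs <- freqs[poly]
  if (is.null(groups)) groups <- rep("all", nrow(calls))
  n <- nrow(calls)
  pairs <- NULL
  for (g in unique(groups)) {
    gi <- which(groups == g)
    if (length(gi) < 2L) next
    ph <- pihat_matrix(calls[gi, , drop = FALSE], freqs)
    hit <- which(upper.tri(ph) & ph > params$relatedness_pihat_threshold,
                 arr.ind = TRUE)
    if (nrow(hit))
      pairs <- rbind(pairs, data.frame(
        id1 = G$samples$id[gi[hit[, 1]]], id2 = G$samples$id[gi[hit[, 2]]],
        pihat = ph[hit], group = g, stringsAsFactors = FALSE))
  }
  drop <- character(0)
  if (!is.null(pairs) && nrow(pairs)) {
    with_seed(params$seed, {
      for (i in seq_len(nrow(pairs))) {
        p1 <- pairs$id1[i]; p2 <- pairs$id2[i]
        if (p1 %in% drop || p2 %in% drop) next
        drop <- c(drop, sample(c(p1, p2), 1L))
      }
    })
  }
  G2 <- if (length(drop)) subset_genotypes(G, samples = !(G$samples$id %in% drop)) else G
  list(G = G2, pairs = pairs,
       report = qc_stage_report("relatedness", nrow(G$calls), ncol(G$calls),
                                G2, drop, character(0)))
}

#' PCA ancestry outlier filter
#'
#' Principal components are computed on an LD-thinned SNP subset of the
#' reference panel (per-SNP centred by twice the reference allele frequency
#' and scaled by `sqrt(2 p (1 - p))`; missing calls mean-imputed for the
#' decomposition only). Study samples are projected onto the first
#' `pca_n_components` components and removed when their Euclidean distance
#' from the reference centroid exceeds `pca_sd_threshold` times the SD of
#' the reference distances.
#'
#' @param G A [genotype_matrix()].
#' @param reference_panel A [genotype_matrix()] of reference samples typed
#'   on (a superset of) the same SNPs, or `NULL` to skip with a warning.
#' @param params [qc_params()].
#' @return List with filtered `G`, stage `report` and the distances.
#' @export
pca_ancestry_filter <- function(G, reference_panel, params = qc_params()) {
  if (is.null(reference_panel)) {
    warning("pca_ancestry_filter: no reference panel; stage skipped")
    return(list(G = G,
                report = qc_stage_report("pca_ancestry", nrow(G$calls),
                                         ncol(G$calls), G)))
  }
  common <- intersect(G$snp_map$id, reference_panel$snp_map$id)
  Gc <- subset_genotypes(G, snps = common)
  keep <- thin_snps(Gc, params$ld_thin_r2, params$ld_thin_window)
  snps <- Gc$snp_map$id[keep]
  R <- reference_panel$calls[, match(snps, reference_panel$snp_map$id), drop = FALSE]
  X <- Gc$calls[, keep, drop = FALSE]
  p <- colMeans(R, na.rm = TRUE) / 2
  ok <- p > 0 & p < 1 & !is.na(p)
  R <- R[, ok, drop = FALSE]; X <- X[, ok, drop = FALSE]; p <- p[ok]
  std <- function(M) {
    Z <- sweep(M, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = nrow(M))
    Z[is.na(Z)] <- 0
    Z
  }
  # decompose reference and study jointly (standardised by reference
  # frequencies) so that any study-specific axis of variation is visible,
  # then measure distances from the reference centroid
  Z <- rbind(std(R), std(X))
  k <- min(params$pca_n_components, ncol(Z), nrow(Z) - 1L)
  pc <- stats::prcomp(Z, center = FALSE, rank. = k)
  ref_sc <- pc$x[seq_len(nrow(R)), seq_len(k), drop = FALSE]
  stu_sc <- pc$x[nrow(R) + seq_len(nrow(X)), seq_len(k), drop = FALSE]
  centroid <- colMeans(ref_sc)
  dist_to <- function(S) sqrt(rowSums(sweep(S, 2, centroid)^2))
  ref_d <- dist_to(ref_sc)
  stu_d <- dist_to(stu_sc)
  cut <- params$pca_sd_threshold * stats::sd(ref_d)
  drop <- G$samples$id[match(Gc$samples$id[stu_d > cut], G$samples$id)]
  G2 <- if (length(drop)) subset_genotypes(G, samples = !(G$samples$id %in% drop)) else G
  list(G = G2, distances = stats::setNames(stu_d, Gc$samples$id),
       cutoff = cut,
       report = qc_stage_report("pca_ancestry", nrow(G$calls), ncol(G$calls),
                                G2, drop, character(0)))
}

#' Genomic inflation factor
#'
#' Lambda is the median of the 1-df association chi-squared statistics
#' divided by 0.4549 (the null median of a chi-squared with one degree of
#' freedom). The caller supplies statistics already restricted to SNPs with
#' MAF above `lambda_maf_min` (see [additive_chisq()]).
#'
#' @param chisq Numeric vector of 1-df chi-squared statistics.
#' @return Lambda (numeric scalar).
#' @export
genomic_inflation <- function(chisq) {
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) < 30)
    warning("genomic_inflation: fewer than 30 statistics; lambda unstable")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Additive-model chi-squared statistics for the inflation factor
#'
#' Squared t statistics from simple linear regression of the phenotype on
#' the additive minor-allele dosage, restricted to SNPs with MAF above
#' `maf_min`.
#'
#' @param G A [genotype_matrix()].
#' @param phenotype Numeric vector aligned with `G` samples, or a phenotype
#'   data frame with `sample_id` and `ga_days`.
#' @param maf_min MAF restriction (default 0.06).
#' @return Named numeric vector of chi-squared statistics.
#' @export
additive_chisq <- function(G, phenotype, maf_min = 0.06) {
  y <- align_phenotype(G, phenotype)
  D <- minor_dosage(G)
  keep <- which(maf(G) > maf_min)
  out <- vapply(keep, function(j) {
    st <- model_statistic(D[, j], y)
    if (st$status != "completed") return(NA_real_)
    st$t_abs^2
  }, numeric(1))
  stats::setNames(out, G$snp_map$id[keep])
}

#' Run the full QC cascade
#'
#' Order: sample/SNP missingness, heterozygosity, relatedness, HWE, PCA
#' ancestry (entity-level filters before statistics that assume clean data).
#'
#' @param G A [genotype_matrix()].
#' @param params [qc_params()].
#' @param groups Optional per-sample group labels for relatedness.
#' @param reference_panel Optional reference [genotype_matrix()] for the PCA
#'   filter; `NULL` skips that stage with a warning.
#' @return List with the final `G`, per-stage `reports`, and a `summary`
#'   data frame of counts per stage.
#' @export
run_qc <- function(G, params = qc_params(), groups = NULL,
                   reference_panel = NULL) {
  reports <- list()
  s1 <- filter_missingness(G, params); reports$missingness <- s1$report
  if (!is.null(groups))
    groups <- groups[match(s1$G$samples$id, G$samples$id)]
  s2 <- filter_heterozygosity(s1$G, params); reports$heterozygosity <- s2$report
  if (!is.null(groups))
    groups <- groups[match(s2$G$samples$id, s1$G$samples$id)]
  s3 <- filter_relatedness(s2$G, params, groups); reports$relatedness <- s3$report
  s4 <- filter_hwe(s3$G, params); reports$hwe <- s4$report
  s5 <- if (is.null(reference_panel)) {
    list(G = s4$G, report = qc_stage_report("pca_ancestry",
                                            nrow(s4$G$calls),
                                            ncol(s4$G$calls), s4$G))
  } else pca_ancestry_filter(s4$G, reference_panel, params)
  reports$pca_ancestry <- s5$report
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(stage = r$stage, n_samples_in = r$n_samples_in,
               n_snps_in = r$n_snps_in, n_samples_out = r$n_samples_out,
               n_snps_out = r$n_snps_out,
               removed_samples = length(r$removed_samples),
               removed_snps = length(r$removed_snps))))
  rownames(summary) <- NULL
  list(G = s5$G, reports = reports, summary = summary)
}
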