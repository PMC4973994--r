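# Pairwise r2 (EM haplotype vs genotype correlation) and greedy clumping
# against a brute-force reference.

test_that("a duplicated SNP column has r2 = 1 under both methods", {
  G <- random_geno(80, 4, seed = 9)
  G$calls[, 2] <- G$calls[, 1]
  expect_equal(pairwise_r2(1, 2, G, "genotype_correlation"), 1,
               tolerance = 1e-9)
  expect_equal(pairwise_r2(1, 2, G, "em_haplotype"), 1, tolerance = 1e-6)
})

test_that("monomorphic SNPs yield NA r2 with a note", {
  G <- tiny_geno(matrix(c(0L, 0L, 0L, 0L, 1L, 2L), 3, 2))
  expect_message(r2 <- pairwise_r2(1, 2, G), "monomorphic")
  expect_true(is.na(r2))
})

test_that("independent blocks show near-zero r2 in large samples", {
  cfg <- sim_config(n_samples = 2000, n_chromosomes = 1, blocks_per_chr = 2,
                    snps_per_block = 2, founder_haplotypes_per_block = 64,
                    recomb_prob = 1, maf_range = c(0.3, 0.5), seed = 33)
  G <- simulate_genotypes(cfg)
  # SNPs 1-2 in block 1, SNPs 3-4 in block 2: pools are independent
  r2 <- pairwise_r2(1, 3, G, "genotype_correlation")
  se <- 1 / sqrt(nrow(G$calls))      # approx SE of r under independence
  expect_lt(sqrt(r2), 3 * se + 0.02)
})

test_that("EM haplotype r2 matches the exhaustive grid-search oracle", {
  set.seed(71)
  worst <- 0
  for (rep_i in 1:40) {
    n <- sample(30:120, 1)
    # draw genotype pairs with real LD by simulating haplotypes
    pA <- runif(1, 0.15, 0.5); pB <- runif(1, 0.15, 0.5)
    d <- runif(1, -0.5, 0.5) * min(pA * (1 - pB), (1 - pA) * pB,
                                   pA * pB, (1 - pA) * (1 - pB))
    f <- c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
           (1 - pA) * (1 - pB) + d)
    hap <- function() sample(1:4, n, replace = TRUE, prob = f)
    h1 <- hap(); h2 <- hap()
    g1 <- (h1 %in% c(1, 2)) + (h2 %in% c(1, 2))
    g2 <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
    if (var(g1) == 0 || var(g2) == 0) next
    em <- litgwas:::em_haplotype_freqs(g1, g2)
    oracle <- r2_grid_oracle(g1, g2)
    worst <- max(worst, abs(em$r2 - oracle))
  }
  expect_lt(worst, 1e-3)
})

test_that("clumping thresholds act exactly at the documented boundaries", {
  # three SNPs: index at 1 Mb, member at 1 Mb + 249999 (in), 1 Mb + 250000 (out)
  set.seed(5)
  base <- rbinom(200, 2L, 0.4)
  calls <- cbind(base, base, base)   # perfect LD so r2 passes
  storage.mode(calls) <- "integer"
  G <- genotype_matrix(
    calls,
    snp_map = data.frame(id = c("idx", "near", "far"), chr = "1",
                         bp = c(1000000L, 1249999L, 1250000L),
                         a1 = "A", a2 = "G"),
    samples = data.frame(id = sprintf("s%03d", 1:200)))
  results <- data.frame(snp = c("idx", "near", "far"),
                        emp_p = c(1e-5, 0.01, 0.01))
  cl <- clump(results, G, clump_params())
  # "far" (p = 0.01) is no index (p >= 5e-4) and sits exactly at 250 kb,
  # so it joins nothing: one clump of {idx, near}
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$index_snp[1], "idx")
  expect_identical(sort(cl$members[[1]]), c("idx", "near"))
  # no SNP below p1: empty output
  cl0 <- clump(data.frame(snp = "idx", emp_p = 0.01), G, clump_params())
  expect_identical(nrow(cl0), 0L)
})

test_that("greedy clumping matches the brute-force reference on random instances", {
  set.seed(2024)
  params <- clump_params(r2_method = "genotype_correlation",
                         founders_only = FALSE)
  for (inst in 1:60) {
    m <- 30
    n <- 60
    n_chr <- sample(1:2, 1)
    G <- random_geno(n, m, seed = inst, n_chr = n_chr)
    # compress positions so the 250 kb window and ties actually matter
    G$snp_map$bp <- as.integer(cumsum(sample(c(1000L, 100000L, 249000L,
                                               250000L), m, replace = TRUE)))
    # correlated columns to exercise the r2 rule
    for (j in sample(2:m, 10)) G$calls[, j] <- G$calls[, j - 1]
    # p-values with deliberate ties and threshold-straddling values
    p <- sample(c(1e-5, 1e-5, 2e-4, 4.9e-4, 5e-4, 0.01, 0.049, 0.05, 0.3),
                m, replace = TRUE)
    results <- data.frame(snp = G$snp_map$id, emp_p = p)
    r2mat <- matrix(NA_real_, m, m)
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      r2 <- suppressMessages(pairwise_r2(a, b, G, "genotype_correlation",
                                         founders_only = FALSE))
      r2mat[a, b] <- r2mat[b, a] <- r2
    }
    oracle <- clump_oracle(p, G$snp_map$chr, G$snp_map$bp, G$snp_map$id,
                           r2mat, params)
    got <- clump(results, G, params)
    expect_identical(nrow(got), length(oracle))
    if (length(oracle)) {
      o_idx <- vapply(oracle, `[[`, character(1), "index")
      expect_identical(got$index_snp, o_idx)
      for (k in seq_along(oracle))
        expect_identical(sort(got$members[[k]]), oracle[[k]]$members)
    }
  }
})

test_that("clump output is invariant to input row order and clumps are disjoint", {
  G <- random_geno(80, 20, seed = 55)
  G$snp_map$bp <- as.integer(seq(1e5, 2e6, length.out = 20))
  for (j in c(4, 9, 14)) G$calls[, j] <- G$calls[, j - 1]
  set.seed(8)
  results <- data.frame(snp = G$snp_map$id,
                        emp_p = sample(c(1e-5, 3e-4, 0.02, 0.6), 20, TRUE))
  params <- clump_params(r2_method = "genotype_correlation")
  c1 <- clump(results, G, params)
  c2 <- clump(results[sample.int(20), ], G, params)
  c1$members <- lapply(c1$members, sort); c2$members <- lapply(c2$members, sort)
  expect_identical(c1, c2)
  all_members <- unlist(c1$members)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_identical(sum(c1$n_snps), length(all_members))
  # every index obeys p1; every member the p2 and r2 rules (post hoc)
  for (k in seq_len(nrow(c1))) {
    expect_lt(c1$index_p[k], params$p1)
    for (msnp in c1$members[[k]]) {
      expect_lt(results$emp_p[results$snp == msnp], params$p2)
      if (msnp != c1$index_snp[k]) {
        r2 <- pairwise_r2(c1$index_snp[k], msnp, G, "genotype_correlation")
        expect_gt(r2, params$r2_min)
      }
    }
  }
})

test_that("singleton clumps get a usable +/-1 kb span", {
  G <- random_geno(50, 2, seed = 3)
  G$snp_map$bp <- c(500000L, 900000L)
  results <- data.frame(snp = G$snp_map$id, emp_p = c(1e-5, 0.8))
  cl <- clump(results, G, clump_params(r2_method = "genotype_correlation"))
  expect_identical(cl$start, 499000L)
  expect_identical(cl$end, 501000L)
})
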