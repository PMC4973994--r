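# QC cascade: missingness, HWE exact test, heterozygosity, relatedness,
# PCA ancestry, genomic inflation.

test_that("HWE exact test matches hand-enumerated small tables", {
  # (0,2,0): configurations {het=2: 2/3, het=0: 1/3}; observed is the mode
  expect_equal(hwe_exact_test(0, 2, 0), 1.0, tolerance = 1e-12)
  # (1,0,1): only the het=0 configuration has probability <= 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # monomorphic SNPs are not an error
  for (n in c(1, 5, 50)) expect_identical(hwe_exact_test(n, 0, 0), 1)
  expect_error(hwe_exact_test(0, 0, 0), "total")
})

test_that("HWE exact test agrees with the enumeration oracle (n <= 50)", {
  worst <- 0
  for (n in c(2, 3, 7, 17, 50)) {
    for (n_het in 0:n) for (n_hom1 in 0:(n - n_het)) {
      n_hom2 <- n - n_het - n_hom1
      d <- abs(hwe_exact_test(n_hom1, n_het, n_hom2) -
                 hwe_oracle(n_hom1, n_het, n_hom2))
      worst <- max(worst, d)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("missingness filter removes the planted sample and SNP only", {
  G <- random_geno(100, 50, seed = 6)
  G$calls[7, sample.int(50, 3)] <- NA_integer_      # 6% missing sample
  G$calls[sample(setdiff(1:100, 7), 4), 12] <- NA_integer_  # 4% missing SNP
  res <- filter_missingness(G, qc_params())
  expect_identical(res$report$removed_samples, "i0007")
  expect_identical(res$report$removed_snps, "rs0012")
  # fully observed matrix: nothing removed
  G2 <- random_geno(30, 10, seed = 1)
  res2 <- filter_missingness(G2, qc_params())
  expect_identical(length(res2$report$removed_samples), 0L)
  expect_identical(length(res2$report$removed_snps), 0L)
})

test_that("missingness filter is idempotent and counts reconcile", {
  G <- random_geno(80, 40, seed = 2, miss_rate = 0.02)
  r1 <- filter_missingness(G, qc_params())
  r2 <- filter_missingness(r1$G, qc_params())
  expect_identical(r2$G$calls, r1$G$calls)
  rep <- r1$report
  expect_identical(rep$n_samples_in - length(rep$removed_samples),
                   rep$n_samples_out)
  expect_identical(rep$n_snps_in - length(rep$removed_snps), rep$n_snps_out)
})

test_that("heterozygosity filter: zero-SD case removes nobody, planted outlier removed", {
  # identical rows -> SD 0 -> none removed
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), each = 10), 10, 4)
  G <- tiny_geno(calls)
  expect_identical(length(filter_heterozygosity(G)$report$removed_samples), 0L)
  # planted all-heterozygous sample among homozygote-rich samples
  set.seed(8)
  calls <- vapply(runif(60, 0.1, 0.3), function(p) rbinom(40, 2, p),
                  integer(40))
  calls[13, ] <- 1L
  G2 <- tiny_geno(calls)
  res <- filter_heterozygosity(G2, qc_params())
  expect_identical(res$report$removed_samples, "s13")
})

test_that("a duplicated sample pair loses exactly one member, fixed by seed", {
  cfg <- sim_config(n_samples = 60, n_chromosomes = 2, blocks_per_chr = 200,
                    snps_per_block = 1, founder_haplotypes_per_block = 64,
                    n_duplicate_pairs = 1, seed = 21)
  G <- simulate_genotypes(cfg)
  res <- filter_relatedness(G, qc_params(relatedness_pihat_threshold = 0.4, seed = 99))
  expect_identical(length(res$report$removed_samples), 1L)
  expect_true(res$report$removed_samples %in% c("ind00001", "ind00060"))
  expect_gt(res$pairs$pihat[1], 0.9)
  res2 <- filter_relatedness(G, qc_params(relatedness_pihat_threshold = 0.4, seed = 99))
  expect_identical(res2$report$removed_samples, res$report$removed_samples)
})

test_that("relatedness comparisons stay within groups", {
  cfg <- sim_config(n_samples = 40, n_chromosomes = 2, blocks_per_chr = 200,
                    snps_per_block = 1, founder_haplotypes_per_block = 64,
                    n_duplicate_pairs = 1, seed = 3)
  G <- simulate_genotypes(cfg)
  # put the duplicate pair in different groups: no within-group pair left
  groups <- rep(c("mother", "child"), 20)
  groups[1] <- "mother"; groups[40] <- "child"
  res <- filter_relatedness(G, qc_params(relatedness_pihat_threshold = 0.4), groups = groups)
  expect_identical(length(res$report$removed_samples), 0L)
})

test_that("PCA filter removes a far-shifted cluster and only that cluster", {
  set.seed(31)
  m <- 120
  p_ref <- runif(m, 0.2, 0.5)
  mk <- function(n, p) vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  ref_calls <- mk(80, p_ref)
  study_calls <- rbind(mk(40, p_ref),
                       mk(6, pmin(0.95, p_ref + 0.45)))  # shifted cluster
  mkG <- function(calls, prefix) genotype_matrix(
    calls,
    snp_map = data.frame(id = sprintf("rs%03d", 1:m), chr = "1",
                         bp = (1:m) * 1000L, a1 = "A", a2 = "C"),
    samples = data.frame(id = sprintf("%s%03d", prefix, seq_len(nrow(calls)))))
  Gref <- mkG(ref_calls, "ref")
  Gstu <- mkG(study_calls, "stu")
  res <- pca_ancestry_filter(Gstu, Gref, qc_params(pca_sd_threshold = 10))
  expect_identical(sort(res$report$removed_samples),
                   sprintf("stu%03d", 41:46))
  # absent panel: skipped with a warning, nothing removed
  expect_warning(res2 <- pca_ancestry_filter(Gstu, NULL, qc_params()),
                 "skipped")
  expect_identical(nrow(res2$G$calls), nrow(Gstu$calls))
})

test_that("genomic inflation is 1 at the null median and scale-equivariant", {
  expect_equal(genomic_inflation(rep(qchisq(0.5, 1), 100)), 1, tolerance = 1e-6)
  x <- rchisq(200, 1)
  expect_equal(genomic_inflation(2 * x), 2 * genomic_inflation(x),
               tolerance = 1e-12)
  expect_warning(genomic_inflation(rchisq(10, 1)), "fewer than 30")
})

test_that("the QC cascade reconciles counts at every stage", {
  cfg <- sim_config(n_samples = 80, n_chromosomes = 2, blocks_per_chr = 200,
                    snps_per_block = 1, founder_haplotypes_per_block = 64,
                    mask_rate = 0.01, mask_sample_idx = 3,
                    mask_sample_rate = 0.2, n_duplicate_pairs = 1, seed = 17)
  G <- simulate_genotypes(cfg)
  out <- run_qc(G, qc_params(relatedness_pihat_threshold = 0.4))
  s <- out$summary
  expect_identical(s$n_samples_in - s$removed_samples, s$n_samples_out)
  expect_identical(s$n_snps_in - s$removed_snps, s$n_snps_out)
  # stages chain: outputs of one stage are inputs of the next
  expect_identical(s$n_samples_in[-1], s$n_samples_out[-nrow(s)])
  # the high-missingness sample and one duplicate member are gone
  expect_true("ind00003" %in% out$reports$missingness$removed_samples)
  expect_identical(length(out$reports$relatedness$removed_samples), 1L)
})
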