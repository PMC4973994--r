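# Interval preparation, hit counting at exact boundaries, matched-interval
# sampling, and the permutation test against an exhaustive placement oracle.

toy_snp_map <- function(m = 20, spacing = 1000L) {
  data.frame(id = sprintf("t%02d", seq_len(m)), chr = "1",
             bp = seq_len(m) * spacing, stringsAsFactors = FALSE)
}

test_that("interval preparation drops gene-less intervals and merges overlaps", {
  gene_map <- data.frame(symbol = c("G1", "G2"), chr = c("1", "1"),
                         start = c(100000L, 400000L), end = c(110000L, 410000L))
  clumps <- data.frame(
    index_snp = c("a", "b", "c", "d"), chr = "1",
    start = c(95000L, 105000L, 300000L, 395000L),
    end   = c(108000L, 120000L, 330000L, 405000L),
    index_p = c(1e-5, 2e-5, 3e-5, 4e-5), n_snps = c(3L, 2L, 4L, 1L),
    stringsAsFactors = FALSE)
  clumps$members <- as.list(clumps$index_snp)
  params <- enrichment_params(gene_offset = 0L)
  out <- suppressMessages(prepare_intervals(clumps, gene_map, params))
  # c is gene-less at offset 0 -> dropped; a and b overlap -> merged
  expect_identical(nrow(out), 2L)
  expect_identical(out$start[1], 95000L)
  expect_identical(out$end[1], 120000L)
  expect_identical(out$n_snps[1], 5L)
  expect_identical(sort(out$source_clumps[[1]]), c("a", "b"))
  # with a 25 kb flank, interval c (gene 70 kb away) is still dropped
  out25 <- suppressMessages(prepare_intervals(clumps, gene_map,
                                              enrichment_params()))
  expect_false(any(vapply(out25$source_clumps, function(s) "c" %in% s,
                          logical(1))))
  expect_error(prepare_intervals(clumps, gene_map[0, ], params), "empty gene map")
})

test_that("interval-gene hits are inclusive at exactly 25 kb", {
  gene_map <- data.frame(symbol = c("GIN", "GEDGE", "GFAR"), chr = "1",
                         start = c(150000L, 50000L, 49999L),
                         end = c(160000L, 75000L, 74999L))
  intervals <- data.frame(chr = "1", start = 100000L, end = 200000L,
                          n_snps = 5L, stringsAsFactors = FALSE)
  params <- enrichment_params(gene_offset = 25000L)
  # GIN inside; GEDGE ends exactly 25,000 bp left of the interval start
  h <- interval_hits(intervals, c("GIN", "GEDGE"), gene_map, params)
  expect_identical(h$T, 1L)
  expect_identical(h$genes_hit, 2L)
  # GFAR ends 25,001 bp away: no hit
  h2 <- interval_hits(intervals, "GFAR", gene_map, params)
  expect_identical(h2$T, 0L)
  # genes absent from the map are ignored with a note
  expect_message(h3 <- interval_hits(intervals, c("GIN", "NOPE"), gene_map,
                                     params), "absent")
  expect_identical(h3$genes_hit, 1L)
})

test_that("matched intervals respect the SNP-count band and are seeded", {
  snp_map <- toy_snp_map(200, 5000L)
  template <- data.frame(chr = "1", start = 100000L, end = 145000L,
                         n_snps = 10L)
  params <- enrichment_params(seed = 5)
  set.seed(5)
  for (i in 1:50) {
    s <- sample_matched_interval(template, snp_map, params)
    expect_gte(s$n_snps, 9L)   # ceil(0.9 * 10)
    expect_lte(s$n_snps, 11L)  # floor(1.1 * 10)
    expect_identical(s$chr, "1")
  }
  set.seed(42); a <- sample_matched_interval(template, snp_map, params)
  set.seed(42); b <- sample_matched_interval(template, snp_map, params)
  expect_identical(a, b)
  # a single-SNP template degenerates to single-SNP intervals
  t1 <- data.frame(chr = "1", start = 100000L, end = 100000L, n_snps = 1L)
  set.seed(7)
  s1 <- sample_matched_interval(t1, snp_map,
                                enrichment_params(span_match = c(0.001, 1000)))
  expect_identical(s1$n_snps, 1L)
  expect_identical(s1$start, s1$end)
})

test_that("permutation p matches the exhaustive placement probability", {
  # 20 evenly spaced SNPs; templates of 3 and 2 SNPs have constant span, so
  # every in-bounds anchor is accepted and placements are uniform
  snp_map <- toy_snp_map(20, 1000L)
  gene_map <- data.frame(symbol = c("GL", "GR"), chr = "1",
                         start = c(1000L, 15000L), end = c(1000L, 16000L))
  sets <- list(left = "GL", both = c("GL", "GR"))
  intervals <- data.frame(chr = "1",
                          start = c(1000L, 14000L), end = c(3000L, 15000L),
                          n_snps = c(3L, 2L), stringsAsFactors = FALSE)
  params <- enrichment_params(gene_offset = 0L, n_permutations = 100000L,
                              span_match = c(0.5, 2), seed = 31)
  res <- enrichment_test(intervals, sets, gene_map, snp_map, params)

  # oracle: enumerate every anchor pair
  anchors <- function(m) 1:(20 - m + 1)
  hit <- function(a, m, genes) {
    s <- a * 1000L; e <- (a + m - 1L) * 1000L
    any(gene_map$start[gene_map$symbol %in% genes] <= e &
          gene_map$end[gene_map$symbol %in% genes] >= s)
  }
  for (nm in names(sets)) {
    T_obs <- interval_hits(intervals, sets[[nm]], gene_map,
                           enrichment_params(gene_offset = 0L))$T
    h1 <- vapply(anchors(3), hit, logical(1), m = 3, genes = sets[[nm]])
    h2 <- vapply(anchors(2), hit, logical(1), m = 2, genes = sets[[nm]])
    pr <- outer(h1, h2, `+`)
    p_exact <- mean(pr >= T_obs)
    got <- res$emp_p[res$set == nm]
    se <- sqrt(p_exact * (1 - p_exact) / params$n_permutations)
    expect_lt(abs(got - p_exact), 3 * se + 2 / params$n_permutations)
  }
})

test_that("estimator bounds and degenerate sets behave", {
  snp_map <- toy_snp_map(20, 1000L)
  gene_map <- data.frame(symbol = "GALL", chr = "1", start = 1L, end = 30000L)
  sets <- list(all = "GALL", ghost = "MISSING")
  intervals <- data.frame(chr = "1", start = 5000L, end = 7000L, n_snps = 3L)
  params <- enrichment_params(gene_offset = 0L, n_permutations = 200L,
                              seed = 2)
  expect_warning(res <- enrichment_test(intervals, sets, gene_map, snp_map,
                                        params), "no genes")
  # every placement hits the genome-spanning gene: p = 1
  expect_identical(res$emp_p[res$set == "all"], 1)
  expect_identical(res$emp_p[res$set == "ghost"], 1)
  expect_true(all(res$emp_p >= 1 / (params$n_permutations + 1)))
})

test_that("enlarging the gene offset never decreases observed hits", {
  set.seed(12)
  gene_map <- data.frame(symbol = sprintf("g%d", 1:8), chr = "1",
                         start = sort(sample.int(5e5, 8)) , end = NA)
  gene_map$end <- gene_map$start + 2000L
  intervals <- data.frame(chr = "1", start = c(50000L, 300000L),
                          end = c(80000L, 330000L), n_snps = c(3L, 3L))
  prev <- -1L
  for (off in c(0L, 5000L, 25000L, 100000L)) {
    T_now <- interval_hits(intervals, gene_map$symbol, gene_map,
                           enrichment_params(gene_offset = off))$T
    expect_gte(T_now, prev)
    prev <- T_now
  }
})

test_that("shared replicates agree with per-set independent replicates", {
  snp_map <- toy_snp_map(40, 2000L)
  gene_map <- data.frame(symbol = c("GA", "GB"), chr = "1",
                         start = c(10000L, 60000L), end = c(12000L, 64000L))
  sets <- list(a = "GA", b = "GB")
  intervals <- data.frame(chr = "1", start = c(8000L, 50000L),
                          end = c(14000L, 56000L), n_snps = c(4L, 4L))
  params <- enrichment_params(gene_offset = 0L, n_permutations = 5000L,
                              seed = 9)
  shared <- enrichment_test(intervals, sets, gene_map, snp_map, params)
  for (nm in names(sets)) {
    pi <- enrichment_params(gene_offset = 0L, n_permutations = 5000L,
                            seed = 100 + match(nm, names(sets)))
    indep <- enrichment_test(intervals, sets[nm], gene_map, snp_map, pi)
    p1 <- shared$emp_p[shared$set == nm]
    p2 <- indep$emp_p[1]
    se <- sqrt(max(p1, p2) / params$n_permutations)
    expect_lt(abs(p1 - p2), 4 * se + 0.01)
  }
})

test_that("null enrichment p-values are roughly uniform for random sets", {
  set.seed(77)
  snp_map <- toy_snp_map(300, 3000L)
  gene_map <- data.frame(symbol = sprintf("g%03d", 1:60), chr = "1",
                         start = seq(5000L, by = 15000L, length.out = 60),
                         end = seq(9000L, by = 15000L, length.out = 60))
  # signal-free target intervals: random anchors
  anchors <- sample.int(290, 8)
  intervals <- data.frame(chr = "1", start = snp_map$bp[anchors],
                          end = snp_map$bp[anchors + 5L], n_snps = 6L)
  sets <- lapply(1:40, function(i) sample(gene_map$symbol, 15))
  names(sets) <- sprintf("s%02d", 1:40)
  res <- enrichment_test(intervals, sets, gene_map, snp_map,
                         enrichment_params(gene_offset = 0L,
                                           n_permutations = 800L, seed = 13))
  # discrete statistics make p super-uniform; check location not shape
  expect_gt(median(res$emp_p), 0.2)
  expect_gt(mean(res$emp_p > 0.05), 0.8)
})
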