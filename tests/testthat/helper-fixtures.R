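# Shared fixture builders (all in code; no stored data).

# a tiny hand-built genotype matrix
tiny_geno <- function(calls = NULL, chr = NULL) {
  if (is.null(calls))
    calls <- matrix(c(0L, 1L, 2L,
                      1L, 1L, 0L,
                      2L, 0L, NA), nrow = 3, byrow = TRUE)
  m <- ncol(calls)
  if (is.null(chr)) chr <- rep("1", m)
  genotype_matrix(
    calls,
    snp_map = data.frame(id = sprintf("snp%02d", seq_len(m)), chr = chr,
                         bp = seq_len(m) * 1000L,
                         a1 = rep("A", m), a2 = rep("G", m),
                         stringsAsFactors = FALSE),
    samples = data.frame(id = sprintf("s%02d", seq_len(nrow(calls))),
                         stringsAsFactors = FALSE))
}

# random genotype matrix with independent SNPs (for property tests)
random_geno <- function(n, m, seed = 1, miss_rate = 0, n_chr = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  calls <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  if (miss_rate > 0) calls[runif(length(calls)) < miss_rate] <- NA_integer_
  chr <- sort(rep_len(as.character(seq_len(n_chr)), m))
  bp <- unlist(lapply(unique(chr), function(cc) seq_len(sum(chr == cc)) * 5000L))
  genotype_matrix(
    calls,
    snp_map = data.frame(id = sprintf("rs%04d", seq_len(m)), chr = chr,
                         bp = bp, a1 = "A", a2 = "C",
                         stringsAsFactors = FALSE),
    samples = data.frame(id = sprintf("i%04d", seq_len(n)),
                         stringsAsFactors = FALSE))
}

# brute-force HWE exact test oracle: enumerate heterozygote configurations
# with lgamma factorials (independent of the recurrence implementation)
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n1 <- 2 * n_hom1 + n_het
  n2 <- 2 * n_hom2 + n_het
  nr <- min(n1, n2)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  logp <- vapply(hets, function(h) {
    homr <- (nr - h) / 2
    homc <- n - h - homr
    lgamma(n + 1) - lgamma(homr + 1) - lgamma(h + 1) - lgamma(homc + 1) +
      h * log(2) +
      lgamma(n1 + 1) + lgamma(n2 + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# brute-force clumping reference: re-derives assignments from the rules,
# with precomputed pairwise r2 passed in to stay independent of clump()
clump_oracle <- function(p, chr, bp, snp, r2mat, params) {
  ord <- order(p, chr, bp)
  assigned <- rep(FALSE, length(p))
  clumps <- list()
  for (i in ord) {
    if (p[i] >= params$p1 || assigned[i]) next
    members <- i
    for (k in seq_along(p)) {
      if (k == i || assigned[k]) next
      if (chr[k] != chr[i]) next
      if (abs(bp[k] - bp[i]) >= params$kb_window * 1000) next
      if (p[k] >= params$p2) next
      r2 <- r2mat[i, k]
      if (!is.na(r2) && r2 > params$r2_min) members <- c(members, k)
    }
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1]] <- list(index = snp[i],
                                         members = sort(snp[members]))
  }
  clumps
}

# exhaustive grid-search oracle for two-locus haplotype ML (free parameter
# f11 within its feasible bounds given allele frequencies)
r2_grid_oracle <- function(g1, g2, grid_n = 4000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  f11s <- seq(lo + 1e-9, hi - 1e-9, length.out = grid_n)
  ll <- vapply(f11s, function(f11) {
    f <- c(f11, pA - f11, pB - f11, 1 - pA - pB + f11)
    if (any(f < 0)) return(-Inf)
    f <- pmax(f, 1e-12)
    pr <- matrix(0, 3, 3)
    pr[3, 3] <- f[1]^2;          pr[3, 2] <- 2 * f[1] * f[2]
    pr[3, 1] <- f[2]^2;          pr[2, 3] <- 2 * f[1] * f[3]
    pr[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
    pr[2, 1] <- 2 * f[2] * f[4]; pr[1, 3] <- f[3]^2
    pr[1, 2] <- 2 * f[3] * f[4]; pr[1, 1] <- f[4]^2
    sum(cnt * log(pmax(pr, 1e-300)))
  }, numeric(1))
  f11 <- f11s[which.max(ll)]
  D <- f11 - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# tiny gene map helper
tiny_gene_map <- function() {
  data.frame(symbol = c("GA1", "GB2", "GC3"),
             chr = c("1", "1", "2"),
             start = c(1000L, 50000L, 1000L),
             end = c(2000L, 60000L, 5000L),
             stringsAsFactors = FALSE)
}
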