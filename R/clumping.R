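# Greedy LD clumping: collapse correlated neighbouring association signals
# into independent loci around index SNPs.

#' Clumping parameters
#'
#' Defaults reproduce the clumping rules this package re-implements: index
#' p < 5e-4, members within 250 kb of the index (strict), r-squared with
#' the index > 0.25 (strict), member p < 0.05; r-squared from EM
#' maximum-likelihood haplotype frequencies computed on founders.
#'
#' @param p1 Index-SNP p-value threshold.
#' @param p2 Member p-value threshold.
#' @param r2_min Minimum squared correlation with the index (strict).
#' @param kb_window Index-to-member distance window in kb (strict).
#' @param r2_method `"em_haplotype"` (EM haplotype-frequency r-squared) or
#'   `"genotype_correlation"` (squared Pearson correlation of dosages).
#' @param founders_only Compute r-squared on founder samples only.
#' @return A `clump_params` list.
#' @export
clump_params <- function(p1 = 5e-4, p2 = 0.05, r2_min = 0.25,
                         kb_window = 250,
                         r2_method = c("em_haplotype", "genotype_correlation"),
                         founders_only = TRUE) {
  stopifnot(r2_min >= 0, r2_min <= 1, kb_window > 0)
  structure(list(p1 = p1, p2 = p2, r2_min = r2_min, kb_window = kb_window,
                 r2_method = match.arg(r2_method),
                 founders_only = isTRUE(founders_only)),
            class = "clump_params")
}

# EM estimate of two-locus haplotype frequencies from unphased genotype
# calls (counts of the A2 allele at each locus). Returns the haplotype
# frequencies, log-likelihood and r^2.
em_haplotype_freqs <- function(g1, g2, max_iter = 50, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  # haplotypes 11, 10, 01, 00 (allele 1 = A2 at that locus)
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  f <- pmax(f, 1e-12); f <- f / sum(f)
  loglik <- function(f) {
    pr <- matrix(0, 3, 3)
    pr[3, 3] <- f[1]^2;            pr[3, 2] <- 2 * f[1] * f[2]
    pr[3, 1] <- f[2]^2;            pr[2, 3] <- 2 * f[1] * f[3]
    pr[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
    pr[2, 1] <- 2 * f[2] * f[4];   pr[1, 3] <- f[3]^2
    pr[1, 2] <- 2 * f[3] * f[4];   pr[1, 1] <- f[4]^2
    sum(cnt * log(pmax(pr, 1e-300)))
  }
  ll <- loglik(f)
  for (it in seq_len(max_iter)) {
    # expected haplotype counts; only the double heterozygote is ambiguous
    h <- numeric(4)
    h[1] <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
    h[2] <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
    h[3] <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]
    h[4] <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
    dh <- cnt[2, 2]
    if (dh > 0) {
      w <- f[1] * f[4] / (f[1] * f[4] + f[2] * f[3])
      h[1] <- h[1] + dh * w; h[4] <- h[4] + dh * w
      h[2] <- h[2] + dh * (1 - w); h[3] <- h[3] + dh * (1 - w)
    }
    f <- h / (2 * n)
    ll_new <- loglik(f)
    if (abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  D <- f[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom <= 0) NA_real_ else min(max(D^2 / denom, 0), 1)
  list(freqs = f, loglik = ll, r2 = r2, n = n)
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared allelic correlation between two SNPs, either from EM
#' maximum-likelihood haplotype frequencies (`em_haplotype`, the default:
#' 50 iterations or log-likelihood change below 1e-10, r^2 =
#' D^2 / (pA qA pB qB)) or as the squared Pearson correlation of genotype
#' dosages. Missing calls are pairwise-deleted. A monomorphic input yields
#' `NA` (treated as below any threshold) with a logged note.
#'
#' @param snp_a,snp_b SNP ids or column indices in `G`.
#' @param G A [genotype_matrix()].
#' @param method `"em_haplotype"` or `"genotype_correlation"`.
#' @param founders_only Restrict to founder samples.
#' @return Squared correlation in `[0, 1]`, or `NA` for monomorphic input.
#' @export
pairwise_r2 <- function(snp_a, snp_b, G,
                        method = c("em_haplotype", "genotype_correlation"),
                        founders_only = TRUE) {
  method <- match.arg(method)
  ja <- if (is.character(snp_a)) match(snp_a, G$snp_map$id) else snp_a
  jb <- if (is.character(snp_b)) match(snp_b, G$snp_map$id) else snp_b
  rows <- if (founders_only) which(G$samples$founder) else seq_len(nrow(G$calls))
  g1 <- G$calls[rows, ja]; g2 <- G$calls[rows, jb]
  ok <- !is.na(g1) & !is.na(g2)
  v1 <- stats::var(g1[ok]); v2 <- stats::var(g2[ok])
  if (is.na(v1) || is.na(v2) || v1 == 0 || v2 == 0) {
    log_note("clump", "monomorphic SNP in r2 computation; returning NA")
    return(NA_real_)
  }
  if (method == "genotype_correlation") {
    r <- stats::cor(g1[ok], g2[ok])
    return(min(r^2, 1))
  }
  em_haplotype_freqs(g1[ok], g2[ok])$r2
}

#' Greedy LD clumping of association results
#'
#' Iterates SNPs with p below `p1` in ascending p (ties by chromosome,
#' then position). Each unassigned index SNP collects every unassigned
#' same-chromosome SNP strictly within `kb_window` kb, with r-squared with
#' the index strictly above `r2_min`, and p below `p2`. A SNP belongs to at
#' most one clump (the first-processed index). Output is ordered by index
#' p. Singleton clumps get a +/-1 kb span so degenerate intervals remain
#' usable downstream.
#'
#' @param results Data frame with at least `snp` and `emp_p` columns (e.g.
#'   from [min_p_combine()]).
#' @param G The [genotype_matrix()] the p-values were computed on (source
#'   of positions and r-squared).
#' @param params [clump_params()].
#' @return Data frame of clumps: `index_snp`, `chr`, `start`, `end`
#'   (1-based inclusive span over members), `index_p`, `n_snps`, and a
#'   list-column `members`.
#' @export
clump <- function(results, G, params = clump_params()) {
  p <- results$emp_p
  snp_idx <- match(results$snp, G$snp_map$id)
  if (anyNA(snp_idx)) stop("clump: results contain SNPs absent from G")
  chr <- G$snp_map$chr[snp_idx]
  bp <- G$snp_map$bp[snp_idx]
  ord <- order(p, chr, bp)
  assigned <- rep(FALSE, nrow(results))
  out <- list()
  cand_idx <- ord[p[ord] < params$p1]
  for (i in cand_idx) {
    if (assigned[i]) next
    same <- which(!assigned &
                    chr == chr[i] &
                    abs(bp - bp[i]) < params$kb_window * 1000 &
                    p < params$p2)
    same <- setdiff(same, i)
    mem <- i
    for (k in same) {
      r2 <- pairwise_r2(snp_idx[i], snp_idx[k], G,
                        method = params$r2_method,
                        founders_only = params$founders_only)
      if (!is.na(r2) && r2 > params$r2_min) mem <- c(mem, k)
    }
    assigned[mem] <- TRUE
    span <- range(bp[mem])
    if (length(mem) == 1L) span <- span + c(-1000L, 1000L)
    out[[length(out) + 1L]] <- data.frame(
      index_snp = results$snp[i], chr = chr[i],
      start = max(1L, span[1]), end = span[2],
      index_p = p[i], n_snps = length(mem), stringsAsFactors = FALSE)
    attr(out[[length(out)]], "members") <- results$snp[mem]
  }
  if (!length(out)) {
    res <- data.frame(index_snp = character(0), chr = character(0),
                      start = integer(0), end = integer(0),
                      index_p = numeric(0), n_snps = integer(0))
    res$members <- list()
    return(res)
  }
  members <- lapply(out, attr, "members")
  res <- do.call(rbind, out)
  res$members <- members
  res <- res[order(res$index_p, res$chr, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select the top clumps by index p-value
#'
#' @param clumps Clump table from [clump()].
#' @param k Number of clumps to keep (default 300).
#' @return The `k` best clumps by index p.
#' @export
top_clumps <- function(clumps, k = 300L) {
  clumps[seq_len(min(k, nrow(clumps))), , drop = FALSE]
}
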