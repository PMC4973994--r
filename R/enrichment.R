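# Interval-based gene-set enrichment of top clumps against an empirical
# null of SNP-density-matched random intervals (a re-implementation of the
# INRICH-style algorithm).

#' Enrichment parameters
#'
#' @param gene_offset Flank added to both sides of every gene when testing
#'   interval-gene overlap (default 25 kb; boundary touching counts).
#' @param n_permutations Null replicates (production default 100,000; the
#'   package desk default is 10,000).
#' @param snp_count_match Fractional band for the SNP count of a matched
#'   random interval relative to its template (default 90-110%).
#' @param span_match Soft fractional band for the physical span (default
#'   0.5-2.0); widened stepwise after `max_resample_attempts` rejections.
#' @param top_k_clumps Number of top clumps fed to enrichment (default 300).
#' @param max_resample_attempts Rejection-sampling attempts per widening
#'   step.
#' @param require_genes_in_null If `TRUE`, random intervals are resampled
#'   until they contain at least one gene (conservative mode; the default
#'   permissive mode allows gene-less random intervals).
#' @param corrected_p If `TRUE`, a second permutation stage computes
#'   FWER-corrected p-values from the per-replicate minimum p across sets.
#' @param seed Integer seed.
#' @return An `enrichment_params` list.
#' @export
enrichment_params <- function(gene_offset = 25000L,
                              n_permutations = 10000L,
                              snp_count_match = c(0.90, 1.10),
                              span_match = c(0.5, 2.0),
                              top_k_clumps = 300L,
                              max_resample_attempts = 1000L,
                              require_genes_in_null = FALSE,
                              corrected_p = FALSE,
                              seed = 1L) {
  stopifnot(n_permutations >= 100, gene_offset >= 0,
            snp_count_match[1] <= 1, snp_count_match[2] >= 1,
            span_match[1] <= 1, span_match[2] >= 1)
  structure(list(gene_offset = as.integer(gene_offset),
                 n_permutations = as.integer(n_permutations),
                 snp_count_match = snp_count_match,
                 span_match = span_match,
                 top_k_clumps = as.integer(top_k_clumps),
                 max_resample_attempts = as.integer(max_resample_attempts),
                 require_genes_in_null = isTRUE(require_genes_in_null),
                 corrected_p = isTRUE(corrected_p),
                 seed = as.integer(seed)),
            class = "enrichment_params")
}

# GRanges helpers (internal coordinates are 1-based inclusive throughout)
intervals_granges <- function(df) {
  GenomicRanges::GRanges(df$chr, IRanges::IRanges(df$start, df$end))
}

gene_flank_granges <- function(gene_map, symbols, offset) {
  gm <- gene_map[gene_map$symbol %in% symbols, , drop = FALSE]
  if (nrow(gm) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(gm$chr,
                         IRanges::IRanges(pmax(1L, gm$start - offset),
                                          gm$end + offset),
                         symbol = gm$symbol)
}

#' Prepare target intervals from top clumps
#'
#' Takes the `top_k_clumps` best clumps by index p, removes intervals that
#' overlap no gene at the configured flank, and merges overlapping spans
#' into non-overlapping intervals (union span, summed SNP counts,
#' provenance recorded).
#'
#' @param clumps Clump table from [clump()].
#' @param gene_map Gene map data frame (`symbol`, `chr`, `start`, `end`).
#' @param params [enrichment_params()].
#' @return Data frame of non-overlapping target intervals: `chr`, `start`,
#'   `end`, `n_snps`, list-column `source_clumps`.
#' @export
prepare_intervals <- function(clumps, gene_map, params = enrichment_params()) {
  if (is.null(gene_map) || nrow(gene_map) == 0L)
    stop("prepare_intervals: empty gene map")
  cl <- top_clumps(clumps, params$top_k_clumps)
  if (nrow(cl) == 0L)
    return(data.frame(chr = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  gr <- intervals_granges(cl)
  genes <- gene_flank_granges(gene_map, gene_map$symbol, params$gene_offset)
  has_gene <- IRanges::overlapsAny(gr, genes)
  n_drop <- sum(!has_gene)
  if (n_drop) log_note("enrich", "removed ", n_drop, " interval(s) without genes")
  cl <- cl[has_gene, , drop = FALSE]
  if (nrow(cl) == 0L)
    return(data.frame(chr = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  gr <- intervals_granges(cl)
  red <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)
  n_snps <- as.integer(tapply(cl$n_snps, grp, sum))
  src <- split(cl$index_snp, grp)
  n_merged <- nrow(cl) - length(red)
  if (n_merged > 0) log_note("enrich", "merged ", nrow(cl), " interval(s) into ",
                             length(red), " non-overlapping interval(s)")
  out <- data.frame(chr = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red),
                    n_snps = n_snps, stringsAsFactors = FALSE)
  out$source_clumps <- unname(src)
  out
}

#' Count interval hits for one gene-set
#'
#' An interval hits a gene when the gene span extended by `gene_offset` on
#' both sides intersects it (boundary touching counts). Genes absent from
#' the map are ignored with a logged count.
#'
#' @param intervals Interval table from [prepare_intervals()].
#' @param gene_set Character vector of gene symbols.
#' @param gene_map Gene map data frame.
#' @param params [enrichment_params()].
#' @return List: `T` (intervals with >= 1 hit), `genes_hit` (distinct set
#'   genes overlapped), `hit_genes` (their symbols).
#' @export
interval_hits <- function(intervals, gene_set, gene_map,
                          params = enrichment_params()) {
  missing_n <- sum(!gene_set %in% gene_map$symbol)
  if (missing_n) log_note("enrich", missing_n,
                          " set gene(s) absent from gene map; ignored")
  genes <- gene_flank_granges(gene_map, gene_set, params$gene_offset)
  if (length(genes) == 0L || nrow(intervals) == 0L)
    return(list(T = 0L, genes_hit = 0L, hit_genes = character(0)))
  gr <- intervals_granges(intervals)
  ov <- GenomicRanges::findOverlaps(gr, genes)
  hit_genes <- unique(genes$symbol[S4Vectors::subjectHits(ov)])
  list(T = length(unique(S4Vectors::queryHits(ov))),
       genes_hit = length(hit_genes),
       hit_genes = sort(hit_genes))
}

# Precomputed SNP-map index for interval sampling: global position/chr
# arrays plus a gene-overlap indicator per possible anchor extent.
snp_map_index <- function(snp_map) {
  ord <- order(snp_map$chr, snp_map$bp)
  list(chr = snp_map$chr[ord], bp = snp_map$bp[ord], n = nrow(snp_map))
}

#' Sample one SNP-density-matched random interval
#'
#' Picks a uniformly random SNP of the analyzed map as the left anchor and
#' extends rightward over `m'` map SNPs, where `m'/m_template` lies in the
#' SNP-count band; the candidate is accepted when it stays on one
#' chromosome and its physical span relative to the template lies in the
#' span band. After `max_resample_attempts` rejections the span band is
#' widened stepwise (doubling, with a log note).
#'
#' @param template One-row interval (needs `n_snps`, `start`, `end`).
#' @param snp_map SNP map data frame (`id`, `chr`, `bp`) of all analyzed
#'   SNPs (the density reference).
#' @param params [enrichment_params()].
#' @return One-row data frame `chr`, `start`, `end`, `n_snps`.
#' @export
sample_matched_interval <- function(template, snp_map,
                                    params = enrichment_params()) {
  idx <- snp_map_index(snp_map)
  s <- sample_matched_batch(template, idx, 1L, params)
  data.frame(chr = s$chr, start = s$start, end = s$end, n_snps = s$n_snps,
             stringsAsFactors = FALSE)
}

# vectorised batch sampler used by the permutation loop; draws `count`
# accepted intervals for one template
sample_matched_batch <- function(template, idx, count, params) {
  m <- max(1L, template$n_snps)
  span_t <- max(1L, template$end - template$start + 1L)
  lo <- max(1L, as.integer(ceiling(params$snp_count_match[1] * m)))
  hi <- max(lo, as.integer(floor(params$snp_count_match[2] * m)))
  widen <- 1
  out_chr <- character(count); out_s <- integer(count)
  out_e <- integer(count); out_m <- integer(count)
  need <- seq_len(count)
  attempts <- 0L
  while (length(need)) {
    k <- length(need)
    a <- sample.int(idx$n, k, replace = TRUE)
    mm <- if (hi > lo) lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
          else rep(lo, k)
    b <- a + mm - 1L
    ok <- b <= idx$n
    ok[ok] <- idx$chr[a[ok]] == idx$chr[b[ok]]
    span <- rep(NA_integer_, k)
    span[ok] <- idx$bp[b[ok]] - idx$bp[a[ok]] + 1L
    ratio <- span / span_t
    ok <- ok & !is.na(ratio) &
      ratio >= params$span_match[1] / widen &
      ratio <= params$span_match[2] * widen
    acc <- need[ok]
    out_chr[acc] <- idx$chr[a[ok]]
    out_s[acc] <- idx$bp[a[ok]]
    out_e[acc] <- idx$bp[b[ok]]
    out_m[acc] <- mm[ok]
    need <- need[!ok]
    attempts <- attempts + 1L
    if (length(need) &&
        attempts %% max(1L, params$max_resample_attempts %/% 50L) == 0L) {
      # batch-level widening: many rejections means the genome cannot host
      # the template at the current span band
      widen <- widen * 2
      log_note("enrich", "widening span band (factor ", widen,
               ") for template of ", m, " SNPs")
      if (widen > 1024)
        stop("sample_matched_interval: no feasible interval for template of ",
             m, " SNPs spanning ", span_t, " bp")
    }
  }
  list(chr = out_chr, start = out_s, end = out_e, n_snps = out_m)
}

#' Interval-based gene-set enrichment test
#'
#' The statistic per set is T, the number of target intervals overlapping
#' at least one set gene (each gene extended by `gene_offset`). Under the
#' null, each replicate replaces every target interval with one
#' SNP-density-matched random interval (one shared replicate serves all
#' sets) and recomputes T. The empirical p is
#' `(1 + #{T_perm >= T_obs}) / (1 + n_permutations)`. Sets with no genes in
#' the map report p = 1 with a warning. With `corrected_p`, a second stage
#' converts each replicate's per-set T into a rank-based p and uses the
#' distribution of the per-replicate minimum to produce FWER-adjusted
#' p-values.
#'
#' @param intervals Interval table from [prepare_intervals()].
#' @param gene_sets A [gene_set_collection()] or named list.
#' @param gene_map Gene map data frame.
#' @param snp_map SNP map (`id`, `chr`, `bp`) of all analyzed SNPs.
#' @param params [enrichment_params()].
#' @return Data frame, one row per set, sorted by `emp_p`: `set`, `n_genes`,
#'   `T_obs`, `genes_hit`, `hit_genes` (comma-joined), `exceedances`,
#'   `emp_p`, and `corr_p` when requested.
#' @export
enrichment_test <- function(intervals, gene_sets, gene_map, snp_map,
                            params = enrichment_params()) {
  stopifnot(nrow(intervals) >= 0, length(gene_sets) >= 1)
  nset <- length(gene_sets)
  obs <- lapply(gene_sets, interval_hits, intervals = intervals,
                gene_map = gene_map, params = params)
  T_obs <- vapply(obs, `[[`, integer(1), "T")
  n_int <- nrow(intervals)
  R <- params$n_permutations
  idx <- snp_map_index(snp_map)
  genes_all <- gene_flank_granges(gene_map, gene_map$symbol, params$gene_offset)

  T_perm <- matrix(0L, R, nset)
  if (n_int > 0) {
    with_seed(params$seed, {
      samp <- vector("list", n_int)
      for (t in seq_len(n_int)) {
        s <- sample_matched_batch(intervals[t, ], idx, R, params)
        if (params$require_genes_in_null) {
          redo <- which(!IRanges::overlapsAny(
            GenomicRanges::GRanges(s$chr, IRanges::IRanges(s$start, s$end)),
            genes_all))
          guard <- 0L
          while (length(redo)) {
            s2 <- sample_matched_batch(intervals[t, ], idx, length(redo), params)
            s$chr[redo] <- s2$chr; s$start[redo] <- s2$start
            s$end[redo] <- s2$end; s$n_snps[redo] <- s2$n_snps
            redo <- redo[!IRanges::overlapsAny(
              GenomicRanges::GRanges(s2$chr, IRanges::IRanges(s2$start, s2$end)),
              genes_all)]
            guard <- guard + 1L
            if (guard > params$max_resample_attempts)
              stop("enrichment_test: cannot find gene-containing null intervals")
          }
        }
        samp[[t]] <- s
      }
      all_gr <- GenomicRanges::GRanges(
        unlist(lapply(samp, `[[`, "chr")),
        IRanges::IRanges(unlist(lapply(samp, `[[`, "start")),
                         unlist(lapply(samp, `[[`, "end"))))
      rep_id <- rep(seq_len(R), times = n_int)
      for (s in seq_len(nset)) {
        genes <- gene_flank_granges(gene_map, gene_sets[[s]],
                                    params$gene_offset)
        if (length(genes) == 0L) next
        hit <- IRanges::overlapsAny(all_gr, genes)
        T_perm[, s] <- as.integer(tabulate(rep_id[hit], nbins = R))
      }
      invisible(NULL)
    })
  }

  exceed <- vapply(seq_len(nset), function(s)
    sum(T_perm[, s] >= T_obs[s]), numeric(1))
  emp_p <- (1 + exceed) / (1 + R)
  empty <- vapply(gene_sets, function(g)
    sum(g %in% gene_map$symbol) == 0L, logical(1))
  if (any(empty)) {
    warning("enrichment_test: ", sum(empty),
            " set(s) with no genes in the gene map; p = 1 reported")
    emp_p[empty] <- 1
  }
  out <- data.frame(set = names(gene_sets),
                    n_genes = lengths(gene_sets),
                    T_obs = T_obs,
                    genes_hit = vapply(obs, `[[`, integer(1), "genes_hit"),
                    hit_genes = vapply(obs, function(o)
                      paste(o$hit_genes, collapse = ","), character(1)),
                    exceedances = exceed, emp_p = emp_p,
                    stringsAsFactors = FALSE)
  if (params$corrected_p) {
    # rank-based per-replicate p per set, then the Westfall-Young null of
    # the per-replicate minimum across sets
    p_rep <- matrix(1, R, nset)
    for (s in seq_len(nset)) {
      Ts <- T_perm[, s]
      sf <- rev(cumsum(rev(tabulate(Ts + 1L, nbins = max(Ts) + 1L))))
      p_rep[, s] <- sf[Ts + 1L] / (1 + R)  # (1 + #{r' != r: T' >= T}) / (1 + R)
    }
    minp <- apply(p_rep, 1, min)
    out$corr_p <- vapply(emp_p, function(p)
      (1 + sum(minp <= p)) / (1 + R), numeric(1))
  }
  out <- out[order(out$emp_p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
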