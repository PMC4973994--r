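#' Genotype matrix container
#'
#' The central container for diploid genotype calls: a samples x SNPs integer
#' matrix counting copies of the A2 allele (0, 1, 2, or `NA` for missing),
#' together with a SNP map (chromosome, 1-based position, alleles) and
#' per-sample metadata.
#'
#' @param calls Integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}` counting copies of allele A2.
#' @param snp_map Data frame with columns `id`, `chr`, `bp` (1-based), `a1`,
#'   `a2`; one row per SNP, same order as `calls` columns.
#' @param samples Data frame with at least a column `id`; optionally
#'   `founder` (logical) and `sex` (1 = male, 2 = female).
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 2L, NA), 2, 2),
#'   snp_map = data.frame(id = c("s1", "s2"), chr = c(1L, 1L),
#'                        bp = c(100L, 200L), a1 = "A", a2 = "G"),
#'   samples = data.frame(id = c("i1", "i2"))
#' )
#' dim(g$calls)
#' @export
genotype_matrix <- function(calls, snp_map, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snp_map <- as.data.frame(snp_map, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("id", "chr", "bp", "a1", "a2")
  if (!all(need %in% names(snp_map)))
    stop("snp_map must have columns: ", paste(need, collapse = ", "))
  if (!"id" %in% names(samples)) stop("samples must have an 'id' column")
  if (nrow(snp_map) != ncol(calls))
    stop("snp_map rows (", nrow(snp_map), ") != calls columns (", ncol(calls), ")")
  if (nrow(samples) != nrow(calls))
    stop("samples rows (", nrow(samples), ") != calls rows (", nrow(calls), ")")
  if (anyDuplicated(snp_map$id)) stop("duplicate SNP ids")
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be 0, 1, 2 or NA")
  for (ch in unique(snp_map$chr)) {
    bp <- snp_map$bp[snp_map$chr == ch]
    if (any(diff(bp) <= 0))
      stop("bp positions not strictly increasing within chromosome ", ch)
  }
  if (!"founder" %in% names(samples)) samples$founder <- TRUE
  rownames(calls) <- samples$id
  colnames(calls) <- snp_map$id
  structure(list(calls = calls, snp_map = snp_map, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$snp_map$chr))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param G A `genotype_matrix`.
#' @param samples Sample ids or logical/integer index; `NULL` keeps all.
#' @param snps SNP ids or logical/integer index; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  si <- seq_len(nrow(G$calls))
  vi <- seq_len(ncol(G$calls))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, G$samples$id) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  if (!is.null(snps)) {
    vi <- if (is.character(snps)) match(snps, G$snp_map$id) else vi[snps]
    if (anyNA(vi)) stop("unknown SNP id(s)")
  }
  genotype_matrix(G$calls[si, vi, drop = FALSE],
                  G$snp_map[vi, , drop = FALSE],
                  G$samples[si, , drop = FALSE])
}

# allele-A2 frequency per SNP (among non-missing calls)
a2_freq <- function(G) {
  colMeans(G$calls, na.rm = TRUE) / 2
}

#' Minor allele frequency per SNP
#'
#' @param G A `genotype_matrix`.
#' @return Named numeric vector of MAFs (NaN for all-missing SNPs).
#' @export
maf <- function(G) {
  f <- a2_freq(G)
  pmin(f, 1 - f)
}

# TRUE where the counted (A2) allele is the minor allele; lexicographic
# tie-break at freq exactly 0.5 (the smaller allele string is "minor").
a2_is_minor <- function(G) {
  f <- a2_freq(G)
  ifelse(abs(f - 0.5) < 1e-12, G$snp_map$a2 < G$snp_map$a1, f < 0.5)
}

# dosage of the minor (effect) allele, samples x SNPs
minor_dosage <- function(G) {
  d <- G$calls
  flip <- !a2_is_minor(G)
  if (any(flip)) d[, flip] <- 2L - d[, flip, drop = FALSE]
  d
}
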