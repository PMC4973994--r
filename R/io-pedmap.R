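# PLINK text PED/MAP reading and writing.
#
# Conventions: MAP is 4 columns (chr, id, cM, bp, 1-based); PED is 6 leading
# columns (FID IID PAT MAT SEX PHENO) followed by two allele tokens per SNP;
# "0 0" encodes a missing call. A plain MAP cannot carry which allele is A1
# and which A2, so write_pedmap() additionally emits an allele-reference TSV
# (snp, a1, a2) that read_pedmap() can consume for an exact round-trip;
# without it, A1 is assigned to the major allele (lexicographic tie-break).

#' Write genotypes as PLINK text PED/MAP
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped`, `<prefix>.map`
#'   and `<prefix>.ref` (allele reference, see Details).
#' @return Invisibly, the three file paths.
#' @details The `.ref` file (columns `snp`, `a1`, `a2`) preserves the A1/A2
#'   assignment, which the PED/MAP pair alone cannot encode; it plays the
#'   role of PLINK's reference-allele file.
#' @export
write_pedmap <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  ref_path <- paste0(prefix, ".ref")
  map <- data.frame(chr = G$snp_map$chr, id = G$snp_map$id, cm = 0,
                    bp = G$snp_map$bp)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(G$calls); m <- ncol(G$calls)
  a1 <- G$snp_map$a1; a2 <- G$snp_map$a2
  # allele tokens per call: 0 -> a1 a1, 1 -> a1 a2, 2 -> a2 a2, NA -> 0 0
  tok <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    g <- G$calls[, j]
    t1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2[j], a1[j]))
    t2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a2[j], a1[j]))
    tok[, 2L * j - 1L] <- t1
    tok[, 2L * j] <- t2
  }
  sex <- if ("sex" %in% names(G$samples)) G$samples$sex else 0L
  lead <- cbind(G$samples$id, G$samples$id, "0", "0", as.character(sex), "-9")
  lines <- apply(cbind(lead, tok), 1, paste, collapse = " ")
  writeLines(lines, ped_path)
  utils::write.table(data.frame(snp = G$snp_map$id, a1 = a1, a2 = a2),
                     ref_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ped = ped_path, map = map_path, ref = ref_path))
}

#' Read PLINK text PED/MAP into a genotype matrix
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param ref_path Optional allele-reference TSV (columns `snp`, `a1`, `a2`)
#'   as written by [write_pedmap()]; if absent, A1 is the major allele
#'   observed in the data (lexicographic tie-break), and monomorphic SNPs get
#'   A2 = `"0"`.
#' @return A [genotype_matrix()].
#' @export
read_pedmap <- function(ped_path, map_path, ref_path = NULL) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  names(map_raw) <- c("chr", "id", "cm", "bp")
  if (anyDuplicated(map_raw$id))
    stop("read_pedmap: duplicate SNP id in MAP: ",
         map_raw$id[duplicated(map_raw$id)][1])
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  for (i in seq_len(n)) {
    if (length(toks[[i]]) != want)
      stop("read_pedmap: ragged PED line ", i, ": expected ", want,
           " fields, found ", length(toks[[i]]))
  }
  tm <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  sample_id <- tm[, 2]
  sex <- suppressWarnings(as.integer(tm[, 5]))
  al1 <- tm[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- tm[, 6L + 2L * seq_len(m), drop = FALSE]

  ref <- NULL
  if (!is.null(ref_path)) {
    ref <- utils::read.table(ref_path, header = TRUE,
                             colClasses = "character")
    ref <- ref[match(map_raw$id, ref$snp), ]
  }
  a1 <- character(m); a2 <- character(m)
  calls <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    x1 <- al1[, j]; x2 <- al2[, j]
    miss <- x1 == "0" | x2 == "0"
    if (!is.null(ref)) {
      a1[j] <- ref$a1[j]; a2[j] <- ref$a2[j]
    } else {
      obs <- c(x1[!miss], x2[!miss])
      tab <- sort(table(obs), decreasing = TRUE)
      if (length(tab) == 0L) { a1[j] <- "0"; a2[j] <- "0" }
      else if (length(tab) == 1L) { a1[j] <- names(tab)[1]; a2[j] <- "0" }
      else {
        two <- names(tab)[1:2]
        if (tab[1] == tab[2]) two <- sort(two)  # major = lexicographically first
        a1[j] <- two[1]; a2[j] <- two[2]
      }
    }
    cnt <- (x1 == a2[j]) + (x2 == a2[j])
    cnt[miss] <- NA_integer_
    bad <- !miss & !(x1 %in% c(a1[j], a2[j]) & x2 %in% c(a1[j], a2[j]))
    if (any(bad))
      stop("read_pedmap: SNP ", map_raw$id[j],
           " has alleles not matching its reference pair")
    calls[, j] <- as.integer(cnt)
  }
  snp_map <- data.frame(id = map_raw$id, chr = map_raw$chr, bp = map_raw$bp,
                        a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(id = sample_id, founder = TRUE, sex = sex,
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, snp_map, samples)
}

#' Read genotypes from a VCF file (read-only alternate source)
#'
#' Thin wrapper over `vcfR`: biallelic sites only, GT field parsed into
#' 0/1/2 counts of the ALT allele (mapped to A2).
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  count_alt <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(is.na(x) | grepl("\\.", x),
           NA_integer_,
           vapply(strsplit(x, "[/|]"),
                  function(a) sum(a == "1"), integer(1)))
  }
  calls <- t(apply(gt, 1, count_alt))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  snp_map <- data.frame(id = ids, chr = fix$CHROM, bp = as.integer(fix$POS),
                        a1 = fix$REF, a2 = fix$ALT, stringsAsFactors = FALSE)
  samples <- data.frame(id = colnames(gt), founder = TRUE,
                        stringsAsFactors = FALSE)
  genotype_matrix(t(calls), snp_map, samples)
}
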