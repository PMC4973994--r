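# Gene coordinate maps. Internal representation is 1-based inclusive
# (columns symbol, chr, start, end); BED files are 0-based half-open and are
# converted exactly at the read/write boundary.

#' Convert BED coordinates to the internal 1-based inclusive system
#'
#' @param start0,end0 BED start (0-based) and end (half-open) coordinates.
#' @return List with `start` and `end`, 1-based inclusive.
#' @export
bed_to_internal <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Convert internal 1-based inclusive coordinates to BED
#'
#' @param start,end 1-based inclusive coordinates.
#' @return List with `start0` and `end0` (0-based half-open).
#' @export
internal_to_bed <- function(start, end) {
  list(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}

#' Read a gene coordinate map (BED or TSV)
#'
#' BED input (`*.bed`, no header: chr, start, end, name) is converted from
#' 0-based half-open; TSV input must have a header with columns `symbol`,
#' `chr`, `start`, `end` already 1-based inclusive.
#'
#' @param path Path to the gene map.
#' @return Data frame with columns `symbol`, `chr`, `start`, `end`.
#' @export
read_gene_map <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = c("character", "integer", "integer",
                                          "character"))
    cc <- bed_to_internal(b[[2]], b[[3]])
    gm <- data.frame(symbol = b[[4]], chr = b[[1]],
                     start = cc$start, end = cc$end,
                     stringsAsFactors = FALSE)
  } else {
    gm <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("symbol", "chr", "start", "end")
    if (!all(need %in% names(gm)))
      stop("read_gene_map: TSV must have columns ", paste(need, collapse = ", "))
    gm <- gm[, need]
    gm$chr <- as.character(gm$chr)
  }
  if (any(gm$end < gm$start)) stop("read_gene_map: end < start")
  gm
}

#' Write a gene map as BED (0-based half-open)
#'
#' @param gene_map Data frame with `symbol`, `chr`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_map_bed <- function(gene_map, path) {
  cc <- internal_to_bed(gene_map$start, gene_map$end)
  utils::write.table(
    data.frame(gene_map$chr, cc$start0, cc$end0, gene_map$symbol),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (is.list(x[[j]]))
    x[[j]] <- vapply(x[[j]], paste, character(1), collapse = ",")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
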