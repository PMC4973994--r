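# GMT gene-set files: one set per line, tab-separated: name, description,
# then gene symbols.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional character vector, one per set.
#' @return A `gene_set_collection` (named list with a `descriptions`
#'   attribute). Duplicate symbols within a set are deduplicated with a
#'   warning; empty sets are retained (enrichment skips them).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  for (nm in names(sets)) {
    s <- as.character(sets[[nm]])
    if (anyDuplicated(s)) {
      warning("gene set '", nm, "': duplicate symbols deduplicated")
      s <- unique(s)
    }
    if (length(s) == 0L)
      warning("gene set '", nm, "' is empty")
    sets[[nm]] <- s
  }
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %s\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read a GMT file
#'
#' @param path Path to a tab-separated GMT file (name, description, symbols).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("read_gmt: line ", bad[1], " has fewer than 2 fields")
  nms <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) if (length(p) > 2L) p[-(1:2)] else character(0))
  names(sets) <- nms
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_set_collection()] or plain named list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
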