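# Abstract corpus I/O: JSON-lines, one abstract per line with fields
# id, title, abstract, optional mesh_terms (array) and label fields.

#' Read an abstract corpus from JSON-lines
#'
#' @param path Path to a `.jsonl` file; each line is a JSON object with at
#'   least `id`, `title` and `abstract`; `mesh_terms` (array of strings) and
#'   arbitrary label fields are preserved.
#' @return Data frame with columns `id`, `title`, `abstract`, list-column
#'   `mesh_terms`, plus any label columns present in every record.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    r <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    if (is.null(r$id)) stop("read_corpus: record on line ", i, " has no id")
    if (is.null(r$abstract))
      stop("read_corpus: record '", r$id, "' is missing the abstract field")
    if (is.null(r$title)) r$title <- ""
    r
  })
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  extra <- setdiff(Reduce(intersect, lapply(recs, names)),
                   c("id", "title", "abstract", "mesh_terms"))
  out <- data.frame(id = ids,
                    title = vapply(recs, function(r) r$title, character(1)),
                    abstract = vapply(recs, function(r) r$abstract, character(1)),
                    stringsAsFactors = FALSE)
  out$mesh_terms <- lapply(recs, function(r) as.character(r$mesh_terms %||% character(0)))
  for (f in extra)
    out[[f]] <- vapply(recs, function(r) as.character(r[[f]]), character(1))
  out
}

#' Write an abstract corpus as JSON-lines
#'
#' @param corpus Data frame as returned by [read_corpus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- as.list(corpus[i, setdiff(names(corpus), "mesh_terms"), drop = FALSE])
    rec <- lapply(rec, function(v) if (is.list(v)) v[[1]] else v)
    rec$mesh_terms <- corpus$mesh_terms[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
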