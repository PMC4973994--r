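# Internal helpers: seeded evaluation, seed derivation, logging.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded package functions do not disturb the session.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stage seed from a global seed and a label
#'
#' Deterministic mixing of a global integer seed with a character label so
#' each pipeline stage and stratum gets an independent, reproducible stream.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed Global integer seed.
#' @param label Character scalar naming the stage/stratum.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# message-based structured log line; counts reconstructible from logs
log_note <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
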