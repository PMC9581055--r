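# Internal condition helpers. Validation/format errors get their own condition
# classes so the command-line front end can map them to exit code 2.

abort_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pathdevfate_validation_error", "pathdevfate_error")))
}

abort_format <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("pathdevfate_format_error",
                                "pathdevfate_validation_error", "pathdevfate_error")))
}

#' Canonicalize gene symbols to the mouse convention
#'
#' Symbols are stripped of surrounding whitespace and re-cased to
#' first-letter-uppercase, remainder lowercase (`"SOX2"` and `"sox2"` both
#' become `"Sox2"`). Expression matrices and curated interaction tables
#' frequently disagree in capitalization; all joins in the pipeline happen on
#' canonical symbols.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of canonical symbols.
#' @export
#' @examples
#' canonical_symbol(c("SOX2", "gata1 ", "Stat5b"))
canonical_symbol <- function(x) {
  x <- trimws(as.character(x))
  bad <- !nzchar(x)
  out <- paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
  out[bad] <- ""
  out
}

# deterministic per-permutation sub-seeds derived from a master seed
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
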