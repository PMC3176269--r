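# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a surface term for dictionary lookup
#'
#' Lowercases, strips punctuation at token boundaries and collapses internal
#' whitespace, so that lookups in the term index are reproducible without a
#' full lexical-variant generator.
#'
#' @param x character vector of surface terms.
#' @return character vector of normalized terms.
#' @export
#' @examples
#' normalize_term("  Cold,  Storage. ")
normalize_term <- function(x) {
  x <- tolower(x)
  # punctuation at token boundaries only: "anti-viral" keeps its hyphen
  x <- gsub("(^|\\s)[[:punct:]]+", "\\1", x)
  x <- gsub("[[:punct:]]+(\\s|$)", "\\1", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Lowercased word tokens, splitting on any non-alphanumeric run.
tokenize_words <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# argmax with deterministic lexicographic tie-break on names.
argmax_lex <- function(scores) {
  stopifnot(length(scores) > 0L, !is.null(names(scores)))
  top <- names(scores)[scores >= max(scores) - 1e-12]
  sort(top)[1L]
}
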