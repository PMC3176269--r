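# Text preprocessing shared by the disambiguators and the summarizer:
# lowercase tokenization, stop-word removal, Porter stemming, counting.

.wsdsumm_env <- new.env(parent = emptyenv())

#' Default English stop-word list
#'
#' A fixed packaged list of uninformative English words, loaded from
#' `inst/extdata/stopwords_en.txt`.  Any file with one word per line can be
#' supplied instead wherever a stop list is accepted.
#'
#' @param path optional path to an alternative one-word-per-line file.
#' @return character vector of stop words.
#' @export
default_stopwords <- function(path = NULL) {
  if (!is.null(path)) {
    return(readLines(path, warn = FALSE, encoding = "UTF-8"))
  }
  if (is.null(.wsdsumm_env$stopwords)) {
    f <- system.file("extdata", "stopwords_en.txt", package = "wsdsumm")
    .wsdsumm_env$stopwords <- readLines(f, warn = FALSE, encoding = "UTF-8")
  }
  .wsdsumm_env$stopwords
}

#' Turn free text into a context vector of stemmed word counts
#'
#' Tokenizes on non-alphanumeric characters, lowercases, removes stop words,
#' applies the Porter stemmer and counts occurrences.  This is the vector
#' representation used for disambiguation contexts and concept profiles.
#'
#' @param text a character string (vectors are concatenated).
#' @param stopwords character vector of stop words to drop before stemming.
#' @return named integer vector: stem -> frequency.  Empty text (or text of
#'   only stop words) gives a zero-length vector.
#' @export
#' @examples
#' preprocess("the cold colds")
preprocess <- function(text, stopwords = default_stopwords()) {
  toks <- tokenize_words(paste(text, collapse = " "))
  toks <- toks[!(toks %in% stopwords)]
  if (length(toks) == 0L) {
    return(setNames(integer(0), character(0)))
  }
  stems <- porter_stem(toks)
  tab <- table(stems)
  setNames(as.integer(tab), names(tab))
}

#' Cosine similarity of two sparse vectors
#'
#' Vectors are named numerics; dimensions are matched by name.  Returns 0
#' when either vector has zero norm, so all-zero contexts never produce NaN.
#'
#' @param a,b named numeric vectors.
#' @return cosine similarity in `[0, 1]` for non-negative vectors.
#' @export
#' @examples
#' cosine_sim(c(x = 1, y = 1), c(x = 1))
cosine_sim <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) return(0)
  sum(a[shared] * b[shared]) / (na * nb)
}
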