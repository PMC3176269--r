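# ROUGE-N and ROUGE-SU: recall-oriented n-gram / skip-bigram overlap
# between a peer summary and one or more reference summaries, with clipped
# matching (each reference n-gram can be matched at most as often as it
# occurs in the peer).

#' Tokenize a summary for ROUGE
#'
#' Lowercases and splits on non-alphanumeric characters.  Stemming and
#' stop-word removal are off by default and can be switched on.
#'
#' @param text character string.
#' @param stem apply the Porter stemmer.
#' @param remove_stopwords drop words from `stopwords`.
#' @param stopwords stop list used when `remove_stopwords` is TRUE.
#' @return character vector of tokens.
#' @export
rouge_tokenize <- function(text, stem = FALSE, remove_stopwords = FALSE,
                           stopwords = default_stopwords()) {
  toks <- tokenize_words(text)
  if (remove_stopwords) toks <- toks[!(toks %in% stopwords)]
  if (stem) toks <- porter_stem(toks)
  toks
}

.as_tokens <- function(x, ...) {
  if (is.character(x) && length(x) == 1L) rouge_tokenize(x, ...) else as.character(x)
}

.ngrams <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1L) return(tokens)
  sapply(seq_len(L - n + 1L), function(i) paste(tokens[i:(i + n - 1L)], collapse = " "))
}

# skip-bigrams: ordered pairs with at most `skip` intervening words,
# optionally together with the unigrams (the "SU" unit set)
.skip_units <- function(tokens, skip, include_unigrams = TRUE) {
  L <- length(tokens)
  units <- if (include_unigrams) tokens else character(0)
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      for (j in (i + 1L):min(L, i + 1L + skip)) {
        units <- c(units, paste(tokens[i], tokens[j]))
      }
    }
  }
  units
}

# recall with clipped counts, summed over references
.rouge_recall <- function(peer_units, ref_units_list) {
  peer_tab <- table(peer_units)
  num <- 0
  den <- 0
  for (ru in ref_units_list) {
    rt <- table(ru)
    shared <- intersect(names(rt), names(peer_tab))
    num <- num + sum(pmin(rt[shared], peer_tab[shared]))
    den <- den + length(ru)
  }
  if (den == 0) stop("no reference units; metric undefined")
  as.numeric(num / den)
}

#' ROUGE-N recall
#'
#' Counts the n-grams shared by the peer and the reference summaries
#' (clipped co-occurrence counts) and divides by the total number of
#' n-grams in the references.  References shorter than `n` tokens are
#' skipped with a warning; if all are skipped the metric is undefined and
#' an error is raised.
#'
#' @param peer peer summary: a single string (tokenized internally) or a
#'   token vector.
#' @param refs list of reference summaries (strings or token vectors).
#' @param n n-gram order (2 for ROUGE-2).
#' @param ... passed to [rouge_tokenize()].
#' @return recall in `[0, 1]`.
#' @export
#' @examples
#' rouge_n("a b c", list("a b d"), n = 2)  # 0.5
rouge_n <- function(peer, refs, n = 2L, ...) {
  stopifnot(length(refs) >= 1L)
  peer_toks <- .as_tokens(peer, ...)
  ref_toks <- lapply(refs, .as_tokens, ...)
  long_enough <- vapply(ref_toks, function(t) length(t) >= n, logical(1))
  if (!all(long_enough)) {
    warning(sum(!long_enough), " reference(s) shorter than n = ", n, " skipped")
  }
  if (!any(long_enough)) stop("all references shorter than n; metric undefined")
  .rouge_recall(.ngrams(peer_toks, n), lapply(ref_toks[long_enough], .ngrams, n))
}

#' ROUGE-SU recall (skip-bigrams plus unigrams)
#'
#' Overlap of skip-bigrams — ordered word pairs with at most `skip`
#' intervening words — between peer and references, clipped matching as in
#' [rouge_n()].  Unigrams are included in the unit set by default (the
#' standard "SU" definition); set `include_unigrams = FALSE` for pure
#' skip-bigram overlap.
#'
#' @inheritParams rouge_n
#' @param skip maximum number of intervening words (4 for ROUGE-SU4).
#' @param include_unigrams include unigrams in the unit multiset.
#' @return recall in `[0, 1]`.
#' @export
rouge_su <- function(peer, refs, skip = 4L, include_unigrams = TRUE, ...) {
  stopifnot(length(refs) >= 1L)
  peer_toks <- .as_tokens(peer, ...)
  ref_toks <- lapply(refs, .as_tokens, ...)
  min_len <- if (include_unigrams) 1L else 2L
  long_enough <- vapply(ref_toks, function(t) length(t) >= min_len, logical(1))
  if (!all(long_enough)) {
    warning(sum(!long_enough), " empty reference(s) skipped")
  }
  if (!any(long_enough)) stop("all references empty; metric undefined")
  .rouge_recall(
    .skip_units(peer_toks, skip, include_unigrams),
    lapply(ref_toks[long_enough], .skip_units, skip, include_unigrams)
  )
}
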