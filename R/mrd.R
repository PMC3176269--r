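# Machine-readable-dictionary disambiguation: each candidate concept gets a
# profile vector built from its definitions, synonyms and directly related
# concepts (siblings excluded), tf x icf weighted; the candidate whose
# profile is most cosine-similar to the context wins.

#' Inverted concept frequency statistics
#'
#' Counts, for every stemmed word, in how many concept profiles (preprocessed
#' [profile_sources()]) of the knowledge base it occurs.  Words spread over
#' many concepts carry little discriminative weight:
#' `icf(w) = log((1 + N) / (1 + n_w)) + 1` with `N` the number of concepts
#' and `n_w` the number of concepts whose sources contain `w`; the smoothed
#' form is strictly positive and equals 1 for a word present in every
#' concept.
#'
#' @param kb a [knowledge_base()].
#' @param stopwords stop list used during preprocessing.
#' @return list with `n_concepts`, `doc_freq` (named integer vector) and the
#'   per-concept preprocessed source vectors in `source_vectors`.
#' @export
concept_icf <- function(kb, stopwords = default_stopwords()) {
  cuis <- names(kb$concepts)
  src <- lapply(cuis, function(k) preprocess(profile_sources(kb, k), stopwords))
  names(src) <- cuis
  df <- table(unlist(lapply(src, names), use.names = FALSE))
  list(
    n_concepts = length(cuis),
    doc_freq = setNames(as.integer(df), names(df)),
    source_vectors = src
  )
}

.icf_weight <- function(words, icf) {
  n_w <- icf$doc_freq[words]
  n_w[is.na(n_w)] <- 0L
  log((1 + icf$n_concepts) / (1 + n_w)) + 1
}

#' Build the profile vector of one concept
#'
#' @param kb a [knowledge_base()].
#' @param cui concept identifier.
#' @param icf statistics from [concept_icf()]; computed on the fly if
#'   missing (quadratic if done per concept — precompute for whole-KB work).
#' @return named numeric vector: stem -> tf x icf weight.  Concepts with no
#'   profile sources give an empty vector.
#' @export
build_concept_profile <- function(kb, cui, icf = NULL) {
  if (is.null(kb$concepts[[cui]])) stop_integrity("unknown cui: ", cui)
  if (is.null(icf)) icf <- concept_icf(kb)
  tf <- icf$source_vectors[[cui]]
  if (length(tf) == 0L) return(setNames(numeric(0), character(0)))
  tf * .icf_weight(names(tf), icf)
}

#' Build profiles for every concept in the knowledge base
#'
#' @inheritParams build_concept_profile
#' @return named list of profile vectors, one per concept.
#' @export
build_concept_profiles <- function(kb, icf = NULL) {
  if (is.null(icf)) icf <- concept_icf(kb)
  out <- lapply(names(kb$concepts), function(k) build_concept_profile(kb, k, icf))
  names(out) <- names(kb$concepts)
  out
}

#' Disambiguate one instance with the MRD method
#'
#' Scores every candidate concept by the cosine similarity between its
#' profile and the preprocessed context, and returns the best one.  Ties
#' (including the all-zero-similarity case) break to the lexicographically
#' smallest CUI, so the method is deterministic.
#'
#' @param kb a [knowledge_base()].
#' @param inst a [wsd_instance()] (candidates of size >= 2).
#' @param profiles named list of profile vectors covering all candidates,
#'   from [build_concept_profiles()].
#' @param stopwords stop list for context preprocessing.
#' @return the selected CUI.
#' @export
mrd_disambiguate <- function(kb, inst, profiles, stopwords = default_stopwords()) {
  cands <- sort(inst$candidates)
  if (length(cands) < 2L) stop("wsd instance must have >= 2 candidate concepts")
  missing <- cands[!cands %in% names(profiles)]
  if (length(missing)) stop_integrity("no profile for candidate: ", paste(missing, collapse = ", "))
  cx <- preprocess(inst$context, stopwords)
  scores <- vapply(cands, function(k) cosine_sim(profiles[[k]], cx), numeric(1))
  argmax_lex(scores)
}
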