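# Automatic-extracted-corpus disambiguation.  For each candidate sense a
# boolean query is built from monosemous relatives (synonyms of the
# candidate joined with OR; the ambiguous term AND monosemous terms of
# related concepts).  Retrieved documents, labeled with the query's
# concept, train a multinomial naive Bayes classifier.

# retrieval-oriented term filters: long terms are unlikely to match, very
# short terms and numbers are almost certainly ambiguous, stop words are
# uninformative
.aec_usable_term <- function(term, stopwords) {
  n <- nchar(term)
  n <= 50L & n >= 3L & !grepl("^[0-9.,]+$", term) &
    !(normalize_term(term) %in% stopwords)
}

# synonyms of `cui` linked to no other concept
.monosemous_synonyms <- function(kb, cui) {
  syn <- kb$concepts[[cui]]$synonyms
  keep <- vapply(syn, function(s) identical(candidate_concepts(kb, s), cui), logical(1))
  sort(syn[keep])
}

#' Build AEC retrieval queries for an ambiguous term
#'
#' For every candidate concept of `term`, constructs a boolean query over
#' titles/abstracts (`[tiab]` field): monosemous synonyms of the candidate
#' joined with OR, plus conjunctions of the ambiguous term with each
#' monosemous term from directly related concepts (one sense per
#' collocation).  Terms longer than 50 characters, shorter than 3, pure
#' numbers and stop words are filtered out.  Quoted phrases are used for
#' precision; `fallback_expression` replaces the quotes by parentheses so
#' the words may match in any position when the exact phrase retrieves
#' nothing.
#'
#' @param kb a [knowledge_base()].
#' @param term an ambiguous surface term (>= 2 candidate concepts).
#' @param stopwords stop list for the term filter.
#' @return list of `aec_query` objects, one per candidate CUI (sorted); a
#'   query with no usable synonyms or relatives has `empty = TRUE` and its
#'   candidate cannot be trained.
#' @export
build_aec_queries <- function(kb, term, stopwords = default_stopwords()) {
  cands <- candidate_concepts(kb, term)
  if (length(cands) < 2L) stop("term is not ambiguous in this knowledge base: ", term)
  rel <- kb$relations
  lapply(cands, function(cui) {
    syns <- setdiff(.monosemous_synonyms(kb, cui), term)
    syns <- syns[.aec_usable_term(syns, stopwords)]
    related <- unique(c(
      rel$source[rel$kind == "is_a" & rel$target == cui],
      rel$target[rel$kind == "is_a" & rel$source == cui],
      rel$target[rel$kind == "other_related" & rel$source == cui],
      rel$source[rel$kind == "other_related" & rel$target == cui]
    ))
    relatives <- character(0)
    for (r in sort(setdiff(related, cui))) {
      relatives <- c(relatives, .monosemous_synonyms(kb, r))
    }
    relatives <- unique(relatives[.aec_usable_term(relatives, stopwords)])

    quote_clause <- function(x) paste0("\"", x, "\"[tiab]")
    paren_clause <- function(x) paste0("(", x, ")[tiab]")
    mk_expr <- function(wrap) {
      clauses <- c(
        wrap(syns),
        if (length(relatives)) {
          paste0("(", wrap(term), " AND ", wrap(relatives), ")")
        }
      )
      paste(clauses, collapse = " OR ")
    }
    structure(
      list(cui = cui, term = term, synonyms = syns, relatives = relatives,
           field = "[tiab]",
           expression = mk_expr(quote_clause),
           fallback_expression = mk_expr(paren_clause),
           empty = length(syns) == 0L && length(relatives) == 0L),
      class = "aec_query"
    )
  })
}

#' @export
print.aec_query <- function(x, ...) {
  cat("<aec_query>", x$cui, if (x$empty) "(empty)" else x$expression, "\n")
  invisible(x)
}

# TRUE for docs containing `phrase` as a contiguous normalized token run
.phrase_match <- function(doc_tokens, phrase) {
  pt <- tokenize_words(phrase)
  np <- length(pt)
  vapply(doc_tokens, function(dt) {
    nd <- length(dt)
    if (np == 0L || nd < np) return(FALSE)
    for (i in seq_len(nd - np + 1L)) {
      if (all(dt[i:(i + np - 1L)] == pt)) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# TRUE for docs containing every token of `phrase`, in any position
.loose_match <- function(doc_tokens, phrase) {
  pt <- tokenize_words(phrase)
  vapply(doc_tokens, function(dt) all(pt %in% dt), logical(1))
}

#' Offline boolean searcher over a local corpus
#'
#' Returns a searcher function with signature
#' `function(query, mode = c("primary", "fallback"))` answering
#' [build_aec_queries()] queries against an in-memory corpus, emulating a
#' title/abstract search service.  In `"primary"` mode quoted phrases must
#' match as contiguous token sequences; in `"fallback"` mode (parenthesized
#' expression) the words of each phrase may occur anywhere in the document.
#' Documents are returned in corpus order.
#'
#' Any function with the same signature and return shape (a data frame with
#' columns `id`, `text`) can replace it, e.g. a live E-utilities client.
#'
#' @param corpus data frame with columns `id` and `text`.
#' @return the searcher function.
#' @export
make_offline_searcher <- function(corpus) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  doc_tokens <- lapply(corpus$text, tokenize_words)
  function(query, mode = c("primary", "fallback")) {
    mode <- match.arg(mode)
    match_fun <- if (mode == "primary") .phrase_match else .loose_match
    hit <- rep(FALSE, nrow(corpus))
    for (s in query$synonyms) hit <- hit | match_fun(doc_tokens, s)
    if (length(query$relatives)) {
      term_hit <- match_fun(doc_tokens, query$term)
      for (r in query$relatives) hit <- hit | (term_hit & match_fun(doc_tokens, r))
    }
    corpus[hit, c("id", "text"), drop = FALSE]
  }
}

#' Collect a pseudo-labeled training corpus
#'
#' Runs each query through the searcher, labels the retrieved documents with
#' the query's concept, and caps the number of documents per concept.  When
#' the primary (quoted-phrase) query retrieves nothing the fallback
#' expression is used; a concept with no documents after the fallback is
#' untrainable and a warning is raised.
#'
#' @param queries list from [build_aec_queries()].
#' @param searcher a searcher function, e.g. [make_offline_searcher()].
#' @param limit maximum documents kept per concept (default 100).
#' @return data frame with columns `cui`, `id`, `text`.
#' @export
collect_training_corpus <- function(queries, searcher, limit = 100L) {
  stopifnot(limit >= 1L)
  out <- list()
  for (q in queries) {
    if (isTRUE(q$empty)) {
      warning("no usable relatives for ", q$cui, "; candidate untrainable")
      next
    }
    docs <- searcher(q, mode = "primary")
    if (nrow(docs) == 0L) docs <- searcher(q, mode = "fallback")
    if (nrow(docs) == 0L) {
      warning("no documents retrieved for ", q$cui, "; candidate untrainable")
      next
    }
    docs <- head(docs, limit)
    out[[q$cui]] <- data.frame(cui = q$cui, id = docs$id, text = docs$text,
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(cui = character(), id = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Train a multinomial naive Bayes sense classifier
#'
#' Bag-of-words multinomial model with add-one smoothing over the
#' preprocessed (stop-listed, stemmed) training documents.  Class priors are
#' proportional to document counts.
#'
#' @param corpus data frame from [collect_training_corpus()] with at least
#'   one document per class.
#' @param stopwords stop list for preprocessing.
#' @return an `nb_model`: `class_log_priors` (named numeric),
#'   `word_log_likelihoods` (classes x vocabulary matrix of log
#'   probabilities) and `vocabulary`.
#' @export
train_nb <- function(corpus, stopwords = default_stopwords()) {
  stopifnot(nrow(corpus) >= 1L)
  classes <- sort(unique(corpus$cui))
  bags <- lapply(seq_len(nrow(corpus)), function(i) preprocess(corpus$text[i], stopwords))
  vocab <- sort(unique(unlist(lapply(bags, names), use.names = FALSE)))
  counts <- matrix(0, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  for (i in seq_len(nrow(corpus))) {
    b <- bags[[i]]
    if (length(b)) counts[corpus$cui[i], names(b)] <- counts[corpus$cui[i], names(b)] + b
  }
  lik <- log(counts + 1) - log(rowSums(counts) + length(vocab))
  priors <- log(as.vector(table(factor(corpus$cui, levels = classes)))) -
    log(nrow(corpus))
  structure(
    list(class_log_priors = setNames(priors, classes),
         word_log_likelihoods = lik,
         vocabulary = vocab),
    class = "nb_model"
  )
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model>", length(x$class_log_priors), "classes,",
      length(x$vocabulary), "vocabulary stems\n")
  invisible(x)
}

#' Disambiguate one instance with a trained AEC model
#'
#' Computes the naive Bayes log posterior of each candidate over the
#' preprocessed context (words outside the training vocabulary are ignored)
#' and returns the argmax; candidates absent from the model (untrainable)
#' are excluded with a warning.  Ties break to the smallest CUI.
#'
#' @param model an `nb_model` from [train_nb()].
#' @param inst a [wsd_instance()].
#' @param stopwords stop list for preprocessing.
#' @return the selected CUI, or `NA` if no candidate has a trained class.
#' @export
aec_disambiguate <- function(model, inst, stopwords = default_stopwords()) {
  cands <- sort(inst$candidates)
  trained <- cands[cands %in% names(model$class_log_priors)]
  if (length(trained) < length(cands)) {
    warning("candidates without training documents excluded: ",
            paste(setdiff(cands, trained), collapse = ", "))
  }
  if (length(trained) == 0L) return(NA_character_)
  cx <- preprocess(inst$context, stopwords)
  cx <- cx[names(cx) %in% model$vocabulary]
  scores <- vapply(trained, function(k) {
    s <- model$class_log_priors[[k]]
    if (length(cx)) s <- s + sum(model$word_log_likelihoods[k, names(cx)] * cx)
    s
  }, numeric(1))
  argmax_lex(scores)
}

#' Train an AEC model for one ambiguous term
#'
#' Convenience wrapper: builds the queries, collects the pseudo-labeled
#' corpus through the searcher and fits the naive Bayes model.
#'
#' @inheritParams build_aec_queries
#' @inheritParams collect_training_corpus
#' @return an `nb_model`, or `NULL` when no candidate is trainable.
#' @export
train_aec <- function(kb, term, searcher, limit = 100L,
                      stopwords = default_stopwords()) {
  queries <- build_aec_queries(kb, term, stopwords)
  corpus <- collect_training_corpus(queries, searcher, limit)
  if (nrow(corpus) == 0L) return(NULL)
  train_nb(corpus, stopwords)
}
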