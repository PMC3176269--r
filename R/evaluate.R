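# Evaluation drivers: accuracy tables for the WSD methods (whole set and
# the JDI-eligible subset) and ROUGE tables for summaries produced under
# the different disambiguation strategies.

#' Predict every instance of a dataset with one WSD method
#'
#' @param kb a [knowledge_base()].
#' @param dataset a [wsd_dataset()].
#' @param method `"mrd"`, `"aec"`, `"jdi"` or `"first_mapping"`.
#' @param profiles concept profiles for MRD (built on demand).
#' @param jd a [jd_model()] for JDI.
#' @param searcher searcher function for AEC; models are trained once per
#'   ambiguous term and reused.
#' @param aec_limit per-concept document cap for AEC training.
#' @param stopwords stop list.
#' @return character vector of predictions (`NA` = abstain), aligned with
#'   the instances.
#' @export
predict_wsd <- function(kb, dataset, method = c("mrd", "aec", "jdi", "first_mapping"),
                        profiles = NULL, jd = NULL, searcher = NULL,
                        aec_limit = 100L, stopwords = default_stopwords()) {
  method <- match.arg(method)
  insts <- dataset$instances
  if (method == "mrd" && is.null(profiles)) profiles <- build_concept_profiles(kb)
  if (method == "jdi" && is.null(jd)) stop("method 'jdi' requires a jd model")
  if (method == "aec" && is.null(searcher)) stop("method 'aec' requires a searcher")
  models <- new.env(parent = emptyenv())
  vapply(insts, function(inst) {
    switch(method,
      first_mapping = sort(inst$candidates)[1L],
      mrd = mrd_disambiguate(kb, inst, profiles, stopwords),
      jdi = jdi_disambiguate(inst, kb, jd, stopwords),
      aec = {
        m <- models[[inst$term]] %||% {
          models[[inst$term]] <- train_aec(kb, inst$term, searcher, aec_limit,
                                           stopwords) %||% NA
          models[[inst$term]]
        }
        if (identical(m, NA)) NA_character_ else aec_disambiguate(m, inst, stopwords)
      }
    )
  }, character(1))
}

#' Accuracy report for several WSD methods
#'
#' Runs each method over the dataset and tabulates accuracy on the whole
#' set and on the JDI-eligible subset (instances whose candidates do not
#' all share one semantic-type set), together with a per-term breakdown.
#'
#' @inheritParams predict_wsd
#' @param methods methods to evaluate.
#' @return list with `summary` (data frame `method`, `set`, `subset`) and
#'   `per_term` (data frame `method`, `term`, `n`, `accuracy`).
#' @export
run_wsd_eval <- function(kb, dataset, methods = c("mrd", "aec", "jdi"),
                         profiles = NULL, jd = NULL, searcher = NULL,
                         aec_limit = 100L, stopwords = default_stopwords()) {
  terms <- vapply(dataset$instances, `[[`, character(1), "term")
  gold <- vapply(dataset$instances, `[[`, character(1), "gold")
  rows <- list()
  per_term <- list()
  for (m in methods) {
    pred <- predict_wsd(kb, dataset, m, profiles = profiles, jd = jd,
                        searcher = searcher, aec_limit = aec_limit,
                        stopwords = stopwords)
    rows[[m]] <- data.frame(
      method = m,
      set = wsd_accuracy(pred, dataset, "all"),
      subset = wsd_accuracy(pred, dataset, "jdi_subset", kb = kb),
      stringsAsFactors = FALSE
    )
    ok <- !is.na(pred) & pred == gold
    agg <- tapply(ok, terms, mean)
    per_term[[m]] <- data.frame(method = m, term = names(agg),
                                n = as.integer(table(terms)[names(agg)]),
                                accuracy = as.numeric(agg),
                                stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       per_term = do.call(rbind, c(per_term, list(make.row.names = FALSE))))
}

#' ROUGE evaluation of summarization under different WSD strategies
#'
#' Summarizes every corpus document once per method, scores the summaries
#' against the reference summaries with ROUGE-2 and ROUGE-SU4, and reports
#' per-document scores, means, per-document win counts and the pairwise
#' relation between disambiguation agreement (proportion of common
#' mappings resolved identically) and the ROUGE-2 difference.
#'
#' @param kb a [knowledge_base()].
#' @param corpus list of documents as produced by [generate_corpus()]
#'   (fields `id`, `sentences`, `reference`).
#' @param methods WSD strategies to compare.
#' @param compression,hub_fraction passed to [summarize_document()].
#' @param profiles,jd,searcher,aec_limit,stopwords method inputs, as in
#'   [predict_wsd()].
#' @return list with `per_document` (data frame `id`, `method`, `rouge2`,
#'   `rouge_su4`), `summary` (means per method), `wins` (documents where
#'   each method achieves the strictly highest ROUGE-2) and `agreement`
#'   (data frame `method_a`, `method_b`, `id`, `agreement`,
#'   `rouge2_diff`).
#' @export
run_summarization_eval <- function(kb, corpus,
                                   methods = c("mrd", "first_mapping"),
                                   compression = 0.30, hub_fraction = 0.1,
                                   profiles = NULL, jd = NULL, searcher = NULL,
                                   aec_limit = 100L,
                                   stopwords = default_stopwords()) {
  if (length(corpus) == 0L) stop("corpus is empty")
  has_ref <- vapply(corpus, function(d) nzchar(d$reference %||% ""), logical(1))
  if (!all(has_ref)) stop("every corpus document needs a reference summary")
  if ("mrd" %in% methods && is.null(profiles)) profiles <- build_concept_profiles(kb)

  per_doc <- list()
  mappings <- list()
  for (m in methods) {
    mappings[[m]] <- list()
    for (doc in corpus) {
      sm <- summarize_document(kb, doc$sentences, wsd = m,
                               compression = compression,
                               hub_fraction = hub_fraction,
                               profiles = profiles, jd = jd,
                               searcher = searcher, aec_limit = aec_limit,
                               stopwords = stopwords)
      mappings[[m]][[doc$id]] <- sm$mappings
      per_doc[[length(per_doc) + 1L]] <- data.frame(
        id = doc$id, method = m,
        rouge2 = rouge_n(sm$summary, list(doc$reference), n = 2L),
        rouge_su4 = rouge_su(sm$summary, list(doc$reference), skip = 4L),
        stringsAsFactors = FALSE
      )
    }
  }
  per_document <- do.call(rbind, c(per_doc, list(make.row.names = FALSE)))
  means <- do.call(rbind, lapply(methods, function(m) {
    sel <- per_document$method == m
    data.frame(method = m,
               mean_rouge2 = mean(per_document$rouge2[sel]),
               mean_rouge_su4 = mean(per_document$rouge_su4[sel]),
               stringsAsFactors = FALSE)
  }))
  r2 <- do.call(cbind, lapply(methods, function(m) {
    per_document$rouge2[per_document$method == m]
  }))
  colnames(r2) <- methods
  wins <- vapply(methods, function(m) {
    sum(apply(r2, 1L, function(x) x[m] > max(x[setdiff(methods, m)])))
  }, numeric(1))

  agreement <- list()
  if (length(methods) >= 2L) {
    for (i in seq_len(length(methods) - 1L)) {
      for (j in (i + 1L):length(methods)) {
        for (doc in corpus) {
          agr <- common_mapping_agreement(mappings[[methods[i]]][[doc$id]],
                                          mappings[[methods[j]]][[doc$id]])
          d <- r2[match(doc$id, vapply(corpus, `[[`, character(1), "id")), ]
          agreement[[length(agreement) + 1L]] <- data.frame(
            method_a = methods[i], method_b = methods[j], id = doc$id,
            agreement = agr, rouge2_diff = d[methods[i]] - d[methods[j]],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(per_document = per_document, summary = means,
       wins = data.frame(method = methods, rouge2_wins = as.integer(wins),
                         stringsAsFactors = FALSE),
       agreement = if (length(agreement)) {
         do.call(rbind, c(agreement, list(make.row.names = FALSE)))
       } else {
         NULL
       })
}
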