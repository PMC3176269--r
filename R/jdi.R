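# Journal-descriptor-indexing disambiguation.  Journal descriptors (JDs)
# carry pre-trained word-probability vectors; semantic types carry a
# pre-computed per-JD score vector.  The context is indexed against the JDs
# and the candidate owning the top-ranked semantic type wins.  Senses that
# share a semantic-type set cannot be separated: the method abstains.

#' Journal-descriptor model
#'
#' Container for the pre-calculated inputs JDI consumes: per-descriptor word
#' probability vectors, and a per-semantic-type indexing over the
#' descriptors.  Training these from literature citations is outside the
#' scope of this package; models are supplied (or generated synthetically
#' with [generate_jd_model()]).
#'
#' @param jd_vectors named list: descriptor id -> named numeric vector of
#'   word probabilities in `[0, 1]`.
#' @param st_jd_index named list: semantic type -> named numeric vector of
#'   per-descriptor scores.
#' @return an object of class `jd_model`.
#' @export
jd_model <- function(jd_vectors, st_jd_index) {
  stopifnot(length(jd_vectors) > 0L, !is.null(names(jd_vectors)))
  for (v in jd_vectors) {
    if (length(v) && (any(v < 0) || any(v > 1))) {
      stop("jd word probabilities must lie in [0, 1]")
    }
  }
  jds <- names(jd_vectors)
  for (st in names(st_jd_index)) {
    bad <- setdiff(names(st_jd_index[[st]]), jds)
    if (length(bad)) {
      stop("st_jd_index for '", st, "' scores unknown descriptor: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(jd_vectors = jd_vectors, st_jd_index = st_jd_index),
            class = "jd_model")
}

#' @export
print.jd_model <- function(x, ...) {
  cat("<jd_model>", length(x$jd_vectors), "descriptors,",
      length(x$st_jd_index), "semantic types indexed\n")
  invisible(x)
}

#' Read / write a journal-descriptor model as JSON
#'
#' @param path JSON file.
#' @return [read_jd_model()]: a [jd_model()].
#' @export
read_jd_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  jd_model(
    jd_vectors = lapply(raw$jd_vectors, function(v) unlist(v)),
    st_jd_index = lapply(raw$st_jd_index, function(v) unlist(v))
  )
}

#' @rdname read_jd_model
#' @param model a [jd_model()].
#' @export
write_jd_model <- function(model, path) {
  jsonlite::write_json(
    list(jd_vectors = lapply(model$jd_vectors, as.list),
         st_jd_index = lapply(model$st_jd_index, as.list)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Disambiguate one instance with the JDI method
#'
#' Indexes the context against each descriptor's word vector (cosine), then
#' scores every semantic type carried by a candidate by the cosine between
#' this per-descriptor score vector and the type's pre-calculated
#' descriptor indexing.  The candidate carrying the top-ranked type is
#' returned.  The method abstains (returns `NA`) when all candidates share
#' an identical semantic-type set, when the context is empty, or when it
#' loads on no descriptor — there is no evidence to rank types.
#'
#' @param inst a [wsd_instance()].
#' @param kb a [knowledge_base()] supplying candidate semantic types.
#' @param jd a [jd_model()] covering every semantic type of the candidates.
#' @param stopwords stop list for context preprocessing.
#' @return the selected CUI, or `NA` (abstain).
#' @export
jdi_disambiguate <- function(inst, kb, jd, stopwords = default_stopwords()) {
  cands <- sort(inst$candidates)
  type_sets <- lapply(cands, function(k) {
    co <- kb$concepts[[k]]
    if (is.null(co)) stop_integrity("unknown cui: ", k)
    co$semantic_types
  })
  names(type_sets) <- cands
  all_types <- sort(unique(unlist(type_sets)))
  uncovered <- setdiff(all_types, names(jd$st_jd_index))
  if (length(uncovered)) {
    stop("jd model does not index semantic type: ", paste(uncovered, collapse = ", "))
  }
  if (all(vapply(type_sets[-1L], identical, logical(1), type_sets[[1L]]))) {
    return(NA_character_)
  }
  cx <- preprocess(inst$context, stopwords)
  if (length(cx) == 0L) return(NA_character_)
  jd_scores <- vapply(jd$jd_vectors, function(v) cosine_sim(cx, v), numeric(1))
  if (all(jd_scores == 0)) return(NA_character_)
  type_scores <- vapply(all_types, function(st) {
    cosine_sim(jd_scores, jd$st_jd_index[[st]])
  }, numeric(1))
  if (all(type_scores == 0)) return(NA_character_)
  top_type <- argmax_lex(type_scores)
  owners <- cands[vapply(type_sets, function(ts) top_type %in% ts, logical(1))]
  sort(owners)[1L]
}
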